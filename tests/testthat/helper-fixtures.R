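# Shared fixtures: built in code, no stored data.

default_cfg <- dls_config()

# diameter grid with an exact 100-nm atom for recovery tests
grid_with_100 <- sort(unique(c(exp(seq(log(1), log(1000), length.out = 64)), 100)))

# two fused 50-nm spheres rendered by hand (centers 48 nm apart)
fused_pair_topograph <- function() {
  z <- matrix(0, 300, 300)
  z <- nanoshell:::render_spheroid(z, 1, 150, 130, 50, 50)
  z <- nanoshell:::render_spheroid(z, 1, 150, 178, 50, 50)
  afm_topograph(z, 1)
}

gold_nominal <- c(5, 10, 30, 40, 50, 60, 80, 100, 150, 200, 250)
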