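# Case-study parameters built in code so core tests do not depend on the
# config layer.
cs_pop <- function(v = 0.067) population_pair(2.99, 0.75, 0, 1, v)
cs_model <- function(u = 0.023, v = 0.067) test_model(cs_pop(v), u)
cs_loss <- function() loss_spec(1, 0, 100, 0, 76)

# thresholds within 5 effective SDs of each population mean: outside this
# band the tail probability being inverted saturates in double precision and
# no inversion can recover the threshold
inversion_grid <- function(m, n = 300) {
  seq(m$pop$mu_d - 5 * sqrt(m$pop$sigma_d^2 + m$u^2),
      m$pop$mu_nd + 5 * sqrt(m$pop$sigma_nd^2 + m$u^2),
      length.out = n)
}

# two identical populations: the test carries no information (chance line)
chance_model <- function(u = 0.1) {
  test_model(population_pair(1, 0.8, 1, 0.8, 0.3), u)
}
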