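# Shared fixtures, all built in code.

# micro instance with the hand-computable worked example
m1 <- micro_instance()

# its (15, 30)-bed configuration used by the accessibility examples
m1_config <- function(beds = c(15, 30)) {
  facility_configuration(c(1, 2), beds, allocate_nearest(m1, c(1, 2)))
}

# a random valid instance/configuration pair for property tests
random_pair <- function(seed, max_I = 12, max_J = 8) {
  set.seed(seed)
  I <- sample(2:max_I, 1)
  J <- sample(2:max_J, 1)
  centers <- data.frame(id = paste0("c", 1:I),
                        x = runif(I, 0, 5000), y = runif(I, 0, 5000),
                        elderly = 1000, demand = sample(5:50, I, replace = TRUE))
  sites <- data.frame(id = paste0("s", 1:J),
                      x = runif(J, 0, 5000), y = runif(J, 0, 5000),
                      max_beds = 300)
  d <- clamp_distances(matrix(runif(I * J, 50, 8000), I, J))
  inst <- build_instance(centers, sites, d, beta = runif(1, 0.8, 2.4))
  p <- sample(seq_len(J - 1), 1)
  open <- sort(sample.int(J, p))
  conf <- size_beds_to_demand(inst, open)
  list(instance = inst, config = conf)
}

# a configuration with a given served demand spread over n facilities,
# one center per facility (for the published profit arithmetic)
.profit_fixture <- function(served, n) {
  base <- served %/% n
  w <- rep(base, n)
  extra <- served - base * n
  if (extra > 0) w[seq_len(extra)] <- w[seq_len(extra)] + 1
  centers <- data.frame(id = paste0("c", 1:n), x = seq_len(n) * 1000, y = 0,
                        elderly = w * 40, demand = w)
  sites <- data.frame(id = paste0("s", 1:n), x = seq_len(n) * 1000, y = 0,
                      max_beds = 300)
  d <- clamp_distances(abs(outer(centers$x, sites$x, "-")))
  inst <- build_instance(centers, sites, d)
  list(instance = inst, config = size_beds_to_demand(inst, 1:n))
}

# a small district scenario for workflow tests
small_scenario <- function(seed = 1) {
  generate_scenario(scenario_spec(seed = seed, I = 25, J = 40,
                                  n_existing = 5, extent = 4000))
}
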