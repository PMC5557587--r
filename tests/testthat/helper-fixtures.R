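# shared fixtures, all built in code

# random truth table of given arity
random_table <- function(arity) {
  truth_table(arity, sample(c(0, 1), 2^arity, replace = TRUE))
}

# brute-force multilinear interpolation straight from Eq-style summation,
# independent of boolcube_eval's implementation details
brute_boolcube <- function(values, xbar) {
  N <- length(xbar)
  total <- 0
  for (r in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(r))[1:N]
    term <- values[r + 1]
    for (i in 1:N)
      term <- term * (bits[i] * xbar[i] + (1 - bits[i]) * (1 - xbar[i]))
    total <- total + term
  }
  total
}

# a 3-species chain A -> B -> C with one inhibiting shortcut A -| C
chain_network <- function() {
  signed_edges(c("A", "B", "A"), c("B", "C", "C"), c(1, 1, -1))
}

# small model: gate params shared (n, k), selectors given
chain_model <- function(w = NULL, n = 3, k = 0.5, tau = 1) {
  hg <- expand_prior_network(chain_network())
  if (is.null(w)) w <- rep(1, length(hg$hyperedges))
  gp <- lapply(hg$hyperedges, function(e)
    cbind(n = rep(n, nrow(e$inputs)), k = rep(k, nrow(e$inputs))))
  logic_ode_model(hg, tau = tau, gate_params = gp, w = w)
}

# a random valid model over a generated network (for property tests)
random_model <- function(seed) {
  truth <- generate_network(n_species = sample(4:8, 1),
                            n_stimuli = sample(1:2, 1),
                            n_inhibitable = 1, seed = seed)
  truth_model <- logic_ode_model(truth$hypergraph, tau = truth$tau,
                                 gate_params = truth$gate_params,
                                 w = truth$w, x0 = truth$x0)
  list(truth = truth, model = truth_model)
}

# the generating model of a ground truth
truth_model_of <- function(truth) {
  logic_ode_model(truth$hypergraph, tau = truth$tau,
                  gate_params = truth$gate_params, w = truth$w,
                  x0 = truth$x0)
}

# encode the ground truth for a problem built on its hypergraph
encode_truth <- function(truth, problem) {
  encode_decision(list(gate_params = truth$gate_params, tau = truth$tau,
                       w = truth$w, x0 = truth$x0), problem)
}
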