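# shared fixtures, built in code at test time

# per-session cache for expensive objects (batches, trained models)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noiseless Gaussian chromatogram on zero background
gaussian_chrom <- function(apex = 5, A = 1000, sigma = 0.05, dt = sigma / 5,
                           span = 6 * sigma) {
  t <- seq(apex - span, apex + span, by = dt)
  tibble::tibble(time = t, intensity = A * exp(-0.5 * ((t - apex) / sigma)^2))
}

# textbook candidate + traces: noise-free Gaussian at the expected RT with a
# proportional qualifier matching the expected ratio, plus a co-eluting ISTD
textbook_traces <- function(apex = 5, A = 1000, sigma = 0.05, ratio = 2) {
  quant <- gaussian_chrom(apex, A, sigma)
  qual <- quant
  qual$intensity <- quant$intensity / ratio
  istd <- quant
  istd$intensity <- quant$intensity * 0.7
  list(quantifier = quant, qualifier = qual, istd = istd)
}

textbook_candidate <- function(traces, params = proc_params()) {
  cand <- find_peak_candidates(traces$quantifier,
                               smoothing_width = params$smoothing_width,
                               border_frac = params$border_frac)
  cand[1L, ]
}

# two-class, clearly separable feature set on the 20-score schema:
# two informative scores, the rest uninformative noise
separable_examples <- function(n = 500, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c(0L, 1L), length.out = n)
    m <- matrix(runif(n * 20, 0.3, 0.7), nrow = n,
                dimnames = list(NULL, qs_names()))
    m[, "qs_t_o"] <- ifelse(lab == 1, runif(n, 0.8, 1), runif(n, 0, 0.2))
    m[, "qs_gauss"] <- ifelse(lab == 1, runif(n, 0.8, 1), runif(n, 0, 0.2))
    out <- tibble::as_tibble(as.data.frame(m))
    out$label <- lab
    out
  })
}

small_batch <- function() {
  cached("small_batch", generate_batch(sim_config(n_samples = 6, n_metabolites = 5,
                                                  noise_sd = 10, seed = 3)))
}

small_result <- function() {
  cached("small_result", process_batch(small_batch()))
}

noise_free_batch <- function() {
  cached("noise_free_batch", generate_batch(
    sim_config(n_samples = 6, n_metabolites = 8, drift_a = 0.005, jitter_sd = 0,
               noise_sd = 0, p_missing = 0, p_decoy = 0, seed = 11)))
}

noise_free_result <- function() {
  cached("noise_free_result", process_batch(noise_free_batch()))
}
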