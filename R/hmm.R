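# Li-Stephens haplotype-copying chain over a reference panel.
#
# States are the H panel haplotypes. At each step the chain stays on its
# current haplotype with probability 1 - rho and switches to a uniformly
# random haplotype (possibly the same one) with probability rho, so the
# transition kernel is (1 - rho) I + rho / H. Emissions at typed sites match
# the copied haplotype's allele with probability 1 - theta; untyped sites
# emit nothing. Forward-backward is run with per-site scaling for numerical
# stability; all chains in a batch are propagated together as B x H matrices.

# Emission matrix for one site: B x H, rows with NA observation are 1.
.ls_emission <- function(obs_t, panel_t, theta) {
  E <- matrix(1, nrow = length(obs_t), ncol = length(panel_t))
  seen <- !is.na(obs_t)
  if (any(seen)) {
    m <- outer(obs_t[seen], panel_t, "==")
    E[seen, ] <- ifelse(m, 1 - theta, theta)
  }
  E
}

# Scaled forward pass for a batch of chains.
# obs: B x L matrix of alleles (0/1) with NA at unobserved sites.
# Returns B x H x L array of scaled forward probabilities (each row sums to 1).
.ls_forward <- function(obs, panel, rho, theta) {
  B <- nrow(obs); L <- ncol(obs); H <- nrow(panel)
  alpha <- array(0, dim = c(B, H, L))
  a <- matrix(1 / H, nrow = B, ncol = H) * .ls_emission(obs[, 1], panel[, 1], theta)
  s <- rowSums(a)
  if (any(s == 0)) stop("zero-probability observation sequence at position 1")
  a <- a / s
  alpha[, , 1] <- a
  if (L > 1) for (t in 2:L) {
    # rows of `a` sum to 1, so the switch term is rho / H for every state
    a <- ((1 - rho) * a + rho / H) * .ls_emission(obs[, t], panel[, t], theta)
    s <- rowSums(a)
    if (any(s == 0)) stop("zero-probability observation sequence at position ", t)
    a <- a / s
    alpha[, , t] <- a
  }
  alpha
}

# Posterior allele-1 probability at every site for a batch of chains.
.ls_posterior_batch <- function(obs, panel, rho, theta) {
  B <- nrow(obs); L <- ncol(obs); H <- nrow(panel)
  alpha <- .ls_forward(obs, panel, rho, theta)
  post <- matrix(0, nrow = B, ncol = L)
  b <- matrix(1, nrow = B, ncol = H)
  g <- alpha[, , L, drop = FALSE]; dim(g) <- c(B, H)
  post[, L] <- (g / rowSums(g)) %*% panel[, L]
  if (L > 1) for (t in (L - 1):1) {
    Eb <- .ls_emission(obs[, t + 1], panel[, t + 1], theta) * b
    b <- (1 - rho) * Eb + (rho / H) * rowSums(Eb)
    b <- b / rowSums(b)
    g <- alpha[, , t, drop = FALSE]; dim(g) <- c(B, H)
    g <- g * b
    post[, t] <- (g / rowSums(g)) %*% panel[, t]
  }
  post
}

# Draw one categorical sample per row of a B x H probability matrix.
.row_sample <- function(P, u) {
  cs <- t(apply(P, 1, cumsum))
  cols <- rowSums(u * cs[, ncol(cs)] > cs) + 1L
  pmin(cols, ncol(cs))
}

# Backward-sample `n_paths` copying paths per chain from stored forward
# probabilities; returns list of B x L matrices of emitted panel alleles.
.ls_sample_batch <- function(obs, panel, rho, theta, n_paths) {
  B <- nrow(obs); L <- ncol(obs); H <- nrow(panel)
  alpha <- .ls_forward(obs, panel, rho, theta)
  lapply(seq_len(n_paths), function(k) {
    alleles <- matrix(0L, nrow = B, ncol = L)
    aL <- alpha[, , L, drop = FALSE]; dim(aL) <- c(B, H)
    state <- .row_sample(aL, stats::runif(B))
    alleles[, L] <- panel[cbind(state, L)]
    if (L > 1) for (t in (L - 1):1) {
      at <- alpha[, , t, drop = FALSE]; dim(at) <- c(B, H)
      # P(s_t = s | s_{t+1}) propto alpha_t(s) * [(1 - rho) I(s = s_{t+1}) + rho / H];
      # rows of alpha_t sum to 1, so the stay probability has closed form.
      a_stay <- at[cbind(seq_len(B), state)]
      p_stay <- (1 - rho) * a_stay / ((1 - rho) * a_stay + rho / H)
      switch_rows <- which(stats::runif(B) >= p_stay)
      for (i in switch_rows) {
        state[i] <- sample.int(H, 1L, prob = at[i, ])
      }
      alleles[, t] <- panel[cbind(state, t)]
    }
    alleles
  })
}

#' Posterior allele probabilities under the haplotype-copying model
#'
#' Runs scaled forward-backward for each observed chain (haplotype) against
#' the reference panel and returns, at every variant (typed and untyped),
#' the posterior probability that the chain carries allele 1.
#'
#' @param observed matrix of observed alleles, chains x typed variants
#'   (0/1), in the order of the typed variants.
#' @param typed logical vector over all variants, TRUE where observed.
#' @param panel `haplotype_panel` (or H x L 0/1 matrix).
#' @param rho per-site copying switch probability, in (0, 1).
#' @param theta per-site mismatch (mutation) probability, in (0, 1).
#' @param batch_size chains processed per forward-backward batch (memory
#'   control only; results are batch-invariant).
#' @return chains x variants matrix of posterior allele-1 probabilities.
#' @export
hmm_posterior <- function(observed, typed, panel, rho, theta,
                          batch_size = 512L) {
  hap <- if (inherits(panel, "haplotype_panel")) panel$haplotypes else panel
  if (nrow(hap) < 1) stop("panel must be nonempty")
  stopifnot(rho > 0, rho < 1, theta >= 0, theta < 1,
            ncol(observed) == sum(typed))
  L <- length(typed)
  obs_full <- matrix(NA_real_, nrow = nrow(observed), ncol = L)
  obs_full[, typed] <- observed
  out <- matrix(0, nrow = nrow(observed), ncol = L)
  starts <- seq(1L, nrow(observed), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, nrow(observed))
    out[idx, ] <- .ls_posterior_batch(obs_full[idx, , drop = FALSE], hap, rho, theta)
  }
  out
}

#' Sample copying paths and emit their alleles
#'
#' Backward-samples `n_paths` state paths per chain from the
#' haplotype-copying posterior and returns the panel alleles along each
#' sampled path (the stochastic counterpart of [hmm_posterior()]).
#'
#' @inheritParams hmm_posterior
#' @param n_paths paths to sample per chain.
#' @param rng_seed integer seed.
#' @return list of `n_paths` chains x variants 0/1 matrices.
#' @export
hmm_sample_alleles <- function(observed, typed, panel, rho, theta, n_paths,
                               rng_seed = 1L, batch_size = 512L) {
  hap <- if (inherits(panel, "haplotype_panel")) panel$haplotypes else panel
  stopifnot(n_paths >= 1, ncol(observed) == sum(typed))
  L <- length(typed)
  obs_full <- matrix(NA_real_, nrow = nrow(observed), ncol = L)
  obs_full[, typed] <- observed
  out <- lapply(seq_len(n_paths), function(k)
    matrix(0L, nrow = nrow(observed), ncol = L))
  withr_seed(rng_seed, {
    starts <- seq(1L, nrow(observed), by = batch_size)
    for (s in starts) {
      idx <- s:min(s + batch_size - 1L, nrow(observed))
      draws <- .ls_sample_batch(obs_full[idx, , drop = FALSE], hap, rho, theta,
                                n_paths)
      for (k in seq_len(n_paths)) out[[k]][idx, ] <- draws[[k]]
    }
  })
  out
}
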