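# Richness and diversity on family-by-sample count tables: rarefaction,
# Chao1, ACE, Shannon, correspondence analysis.

#' Analytic rarefaction
#'
#' Expected number of taxa observed in a random subsample of `n` of the `N`
#' individuals, computed hypergeometrically via log-gamma arithmetic:
#' `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`. A seeded Monte-Carlo mode
#' exists for cross-checking the analytic form.
#'
#' @param counts Non-negative per-taxon abundances.
#' @param depths Subsample sizes, each at most `sum(counts)`.
#' @param method `"analytic"` (default, deterministic) or `"montecarlo"`.
#' @param n_rep,seed Monte-Carlo replicate count and seed.
#' @return Data frame `depth`, `richness`.
#' @export
rarefaction <- function(counts, depths, method = c("analytic", "montecarlo"),
                        n_rep = 200L, seed = 1L) {
  method <- match.arg(method)
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths < 0) || any(depths > N)) stop("depths must lie in [0, N]")
  if (method == "analytic") {
    rich <- vapply(depths, function(n) {
      sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
    }, 0)
  } else {
    set.seed(seed)
    pool <- rep.int(seq_along(counts), counts)
    rich <- vapply(depths, function(n) {
      mean(vapply(seq_len(n_rep), function(i)
        length(unique(sample(pool, n))), 0L))
    }, 0)
  }
  data.frame(depth = depths, richness = rich)
}

count_freqs <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all counts are zero")
  counts
}

#' Chao1 richness estimator with standard error
#'
#' With F1 singletons and F2 doubletons: `S_obs + F1^2 / (2 F2)` when
#' F2 > 0, and the bias-corrected `S_obs + F1 (F1 - 1) / 2` when F2 = 0.
#' The variance follows the classical formula matching the branch used; the
#' branch is reported.
#'
#' @param counts Per-taxon abundances.
#' @return List: `estimate`, `se`, `s_obs`, `F1`, `F2`, `branch`.
#' @export
chao1 <- function(counts) {
  counts <- count_freqs(counts)
  s_obs <- length(counts)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  if (F2 > 0) {
    est <- s_obs + F1^2 / (2 * F2)
    r <- F1 / F2
    v <- F2 * (r^2 / 2 + r^3 + r^4 / 4)
    branch <- "classic"
  } else {
    est <- s_obs + F1 * (F1 - 1) / 2
    v <- if (F1 > 0)
      F1 * (F1 - 1) / 2 + F1 * (2 * F1 - 1)^2 / 4 - F1^4 / (4 * est)
    else 0
    branch <- "bias_corrected"
  }
  list(estimate = est, se = sqrt(max(v, 0)), s_obs = s_obs,
       F1 = F1, F2 = F2, branch = branch)
}

ace_point <- function(Fi, s_abund) {
  # Fi = counts of taxa seen i times, i = 1..cutoff (continuous for the
  # delta-method gradient); returns NA when coverage is zero
  i <- seq_along(Fi)
  s_rare <- sum(Fi)
  n_rare <- sum(i * Fi)
  c_ace <- 1 - Fi[1] / n_rare
  if (c_ace <= 0) return(NA_real_)
  g2 <- max(s_rare * sum(i * (i - 1) * Fi) / (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + Fi[1] * g2 / c_ace
}

#' ACE richness estimator with standard error
#'
#' Abundance-based coverage estimator: taxa with at most `rare_cutoff`
#' individuals form the rare group, coverage is `1 - F1 / N_rare`, and the
#' estimate is `S_abund + S_rare / C + F1 * gamma^2 / C` with the squared
#' coefficient of variation `gamma^2` floored at zero. The standard error is
#' a delta-method approximation: the gradient of the estimator in the
#' rare-frequency counts (computed numerically) against the multinomial-style
#' covariance `Cov(F_i, F_j) = F_i (1[i=j] - F_j / S_est)`. When every rare
#' taxon is a singleton the coverage is zero and the function falls back to
#' [chao1()], flagged in the result.
#'
#' @param counts Per-taxon abundances.
#' @param rare_cutoff Rare/abundant split (default 10).
#' @return List: `estimate`, `se`, `s_obs`, `s_rare`, `s_abund`, `c_ace`,
#'   `fallback` (TRUE when Chao1 was substituted).
#' @export
ace <- function(counts, rare_cutoff = 10L) {
  counts <- count_freqs(counts)
  s_obs <- length(counts)
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  if (!length(rare))
    return(list(estimate = s_obs, se = 0, s_obs = s_obs, s_rare = 0,
                s_abund = s_abund, c_ace = 1, fallback = FALSE))
  i <- seq_len(rare_cutoff)
  Fi <- vapply(i, function(k) sum(rare == k), 0)
  est <- ace_point(Fi, s_abund)
  if (is.na(est)) {
    ch <- chao1(counts)
    return(list(estimate = ch$estimate, se = ch$se, s_obs = s_obs,
                s_rare = length(rare), s_abund = s_abund, c_ace = 0,
                fallback = TRUE))
  }
  grad <- vapply(i, function(k) {
    h <- 1e-5
    Fp <- Fi; Fp[k] <- Fp[k] + h
    Fm <- Fi; Fm[k] <- max(Fm[k] - h, 0)
    ep <- ace_point(Fp, s_abund); em <- ace_point(Fm, s_abund)
    if (is.na(ep) || is.na(em)) 0 else (ep - em) / (Fp[k] - Fm[k])
  }, 0)
  covm <- diag(Fi, length(Fi)) - outer(Fi, Fi) / est
  v <- drop(t(grad) %*% covm %*% grad)
  list(estimate = est, se = sqrt(max(v, 0)), s_obs = s_obs,
       s_rare = length(rare), s_abund = s_abund,
       c_ace = 1 - Fi[1] / sum(i * Fi), fallback = FALSE)
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum p_i ln p_i` with `0 ln 0 = 0`; the family-level values in the
#' 1.5-2.4 range reported for gut communities of about twenty families are
#' on this natural-log scale.
#'
#' @param counts Per-taxon abundances.
#' @return Scalar H.
#' @export
shannon <- function(counts) {
  counts <- count_freqs(counts)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Per-sample diversity table
#'
#' Applies S_obs, Shannon, Chao1 (with SE and branch) and ACE (with SE and
#' fallback flag) to every column of a taxon-by-sample count matrix.
#'
#' @param counts Taxon x sample count matrix (an `uc_` bin, if present, is
#'   excluded from richness but kept for no column).
#' @param rare_cutoff Passed to [ace()].
#' @return Data frame, one row per sample.
#' @export
diversity_table <- function(counts, rare_cutoff = 10L) {
  keep <- !startsWith(rownames(counts), "uc_")
  counts <- counts[keep, , drop = FALSE]
  out <- lapply(colnames(counts), function(s) {
    x <- counts[, s]
    ch <- chao1(x)
    ac <- ace(x, rare_cutoff)
    data.frame(sample = s, s_obs = ch$s_obs, shannon = shannon(x),
               chao1 = ch$estimate, se_chao1 = ch$se,
               chao1_branch = ch$branch,
               ace = ac$estimate, se_ace = ac$se,
               ace_fallback = ac$fallback, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correspondence analysis of a contingency table
#'
#' Classical CA by SVD of the standardized residuals
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` of the correspondence matrix
#' `P = X / n`; principal coordinates are `D_r^{-1/2} U Sigma` (rows) and
#' `D_c^{-1/2} V Sigma` (columns), and the total inertia `sum sigma^2`
#' equals Pearson's chi-square over n. Axis orientation is fixed by making
#' the first nonzero column loading of each axis positive. All-zero rows or
#' columns are dropped with a warning.
#'
#' @param x A non-negative matrix (e.g. family x sample counts).
#' @return An object of class `ca_result`: `row_coords`, `col_coords`,
#'   `singular_values`, `inertia_fractions`, `total_inertia`.
#' @export
correspondence_analysis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative")
  zr <- rowSums(x) == 0
  zc <- colSums(x) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero rows and ", sum(zc),
            " all-zero columns")
    x <- x[!zr, !zc, drop = FALSE]
  }
  n <- sum(x)
  if (n == 0) stop("rank-0 table")
  P <- x / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  K <- min(nrow(x), ncol(x)) - 1L
  K <- max(K, 0L)
  d <- sv$d[seq_len(K)]
  U <- sv$u[, seq_len(K), drop = FALSE]
  V <- sv$v[, seq_len(K), drop = FALSE]
  for (a in seq_len(K)) {
    nz <- which(abs(V[, a]) > 1e-12)
    if (length(nz) && V[nz[1L], a] < 0) {
      V[, a] <- -V[, a]
      U[, a] <- -U[, a]
    }
  }
  row_coords <- diag(1 / sqrt(r)) %*% U %*% diag(d, K)
  col_coords <- diag(1 / sqrt(cc)) %*% V %*% diag(d, K)
  dimnames(row_coords) <- list(rownames(x), paste0("CA", seq_len(K)))
  dimnames(col_coords) <- list(colnames(x), paste0("CA", seq_len(K)))
  ti <- sum(d^2)
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 singular_values = d,
                 inertia_fractions = if (ti > 0) d^2 / ti else d^2,
                 total_inertia = ti),
            class = "ca_result")
}
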