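#' Differential-occupancy configuration
#'
#' Thresholds and numerical policy for per-position differential
#' histone-mark calling. A position is significant when its absolute
#' log2 fold change exceeds `lfc_threshold` and its local FDR is
#' strictly below `lfdr_threshold`. The defaults (0.05 and 0.2) are the
#' calibration at which a self-comparison of replicate groups of the
#' same strain yields no calls.
#'
#' @param lfc_threshold log2 fold-change threshold (> 0; two-sided).
#' @param lfdr_threshold local FDR threshold (> 0; strict inequality).
#' @param dispersion_floor lower bound on the NB dispersion.
#' @param zero_pseudo expected-count floor used when one condition is
#'   all zero (continuity policy; in units of normalised counts).
#' @return A `differential_config` object.
#' @export
differential_config <- function(lfc_threshold = 0.05, lfdr_threshold = 0.2,
                                dispersion_floor = 1e-8, zero_pseudo = 0.5) {
  stopifnot(lfc_threshold > 0, lfdr_threshold > 0)
  structure(list(lfc_threshold = lfc_threshold,
                 lfdr_threshold = lfdr_threshold,
                 dispersion_floor = dispersion_floor,
                 zero_pseudo = zero_pseudo),
            class = "differential_config")
}

#' Per-position nucleosome count matrix around the TSS
#'
#' For each sample, midpoints are collected at every TSS-relative
#' position (oriented in the direction of transcription) and summed
#' over genes, giving an integer positions-by-samples matrix. Positions
#' with zero counts in every sample are dropped. The per-gene average
#' (`counts / n_genes`) is a reporting transform available via
#' [per_gene_average()]; testing uses the integer sums.
#'
#' @param midpoint_list named list of midpoint data.frames (one per
#'   sample, as from [midpoints()]).
#' @param genome a [genome_model()].
#' @param window TSS-relative window, default `c(-1000, 1500)`.
#' @param samples data.frame describing the columns: `sample_id`,
#'   `condition`, `is_input`, `pair_id` (the biological replicate that
#'   links each IP sample to its input). Defaults to all-IP samples in
#'   list order.
#' @return A `position_count_matrix`: list with `positions`, `counts`
#'   (integer matrix), `samples`, `n_genes`.
#' @export
build_position_counts <- function(midpoint_list, genome,
                                  window = c(-1000L, 1500L),
                                  samples = NULL) {
  stopifnot(is.list(midpoint_list), length(midpoint_list) >= 1,
            !is.null(names(midpoint_list)))
  if (window[2] <= window[1]) stop("empty window")
  if (is.null(samples))
    samples <- data.frame(sample_id = names(midpoint_list),
                          condition = "A", is_input = FALSE,
                          pair_id = names(midpoint_list),
                          stringsAsFactors = FALSE)
  if (!all(samples$sample_id %in% names(midpoint_list)))
    stop("samples table names a sample without midpoints")
  cols <- lapply(samples$sample_id, function(s) {
    tr <- build_track(midpoint_list[[s]], genome)
    pr <- tss_profile(tr, genome, window)
    pr$counts
  })
  m <- do.call(cbind, cols)
  colnames(m) <- samples$sample_id
  keep <- rowSums(m) > 0
  structure(list(positions = seq.int(window[1], window[2])[keep],
                 counts = matrix(as.integer(round(m[keep, , drop = FALSE])),
                                 nrow = sum(keep),
                                 dimnames = list(NULL, samples$sample_id)),
                 samples = samples, n_genes = nrow(genome$genes)),
            class = "position_count_matrix")
}

#' @rdname build_position_counts
#' @param pcm a `position_count_matrix`.
#' @return [per_gene_average()] returns the counts matrix divided by
#'   the number of genes (average nucleosomes per gene per position).
#' @export
per_gene_average <- function(pcm) {
  stopifnot(inherits(pcm, "position_count_matrix"))
  pcm$counts / pcm$n_genes
}

#' Input-derived per-position normalisation factors
#'
#' For every IP sample, the paired chromatin-input counts serve as
#' per-position normalisation factors after being scaled by the
#' coverage ratio between the IP and input datasets
#' (`total IP reads / total input reads`). These factors absorb
#' position-level technical biases — chromatin solubility, MNase
#' accessibility, preferential PCR amplification — that the input lane
#' shares with the IP. Zero input counts are replaced by the
#' position-wise minimum positive input count (falling back to the
#' sample-wise minimum), and each factor column is rescaled to
#' geometric mean one so that factors only carry relative,
#' position-level information.
#'
#' @param pcm a `position_count_matrix` whose `samples` table contains
#'   both IP (`is_input = FALSE`) and input samples, linked by
#'   `pair_id`.
#' @return Positive numeric matrix, positions by IP samples.
#' @export
normalization_factors <- function(pcm) {
  stopifnot(inherits(pcm, "position_count_matrix"))
  sm <- pcm$samples
  ips <- sm$sample_id[!sm$is_input]
  inputs <- sm$sample_id[sm$is_input]
  if (!length(inputs)) stop("no input samples in the count matrix")
  imat <- pcm$counts[, inputs, drop = FALSE]
  if (all(imat == 0)) stop("input counts are all zero")
  # position-wise minimum positive input count (fallback: global min)
  pos_min <- apply(imat, 1, function(r) if (any(r > 0)) min(r[r > 0]) else NA)
  global_min <- min(imat[imat > 0])
  pos_min[is.na(pos_min)] <- global_min
  out <- matrix(NA_real_, nrow(imat), length(ips),
                dimnames = list(NULL, ips))
  for (s in ips) {
    pid <- sm$pair_id[sm$sample_id == s]
    inp <- sm$sample_id[sm$is_input & sm$pair_id == pid]
    if (length(inp) != 1)
      stop("IP sample ", s, " has no unique paired input (pair_id ", pid, ")")
    ic <- pcm$counts[, inp]
    if (sum(ic) == 0) stop("paired input for ", s, " is empty")
    ic <- ifelse(ic == 0, pos_min, ic)
    f <- ic * (sum(pcm$counts[, s]) / sum(pcm$counts[, inp]))
    out[, s] <- f / exp(mean(log(f)))
  }
  out
}

# --- negative-binomial Wald machinery -------------------------------------

# Vectorised Newton solve of the per-position NB mean parameter q for one
# condition: counts K (positions x reps), factors f, dispersion alpha
# (per position). Model: K_ij ~ NB(mean = f_ij * q_i, dispersion alpha_i).
nb_fit_q <- function(K, f, alpha, zero_pseudo = 0.5) {
  q <- rowSums(K) / rowSums(f)                 # Poisson MLE start
  zero <- q <= 0
  q[zero] <- zero_pseudo / rowSums(f)[zero]    # continuity for all-zero rows
  for (it in 1:50) {
    mu <- f * q
    denom <- 1 + alpha * mu
    score <- rowSums(f * (K - mu) / (mu * denom)) * q   # d loglik / d log q
    info <- rowSums(mu / denom)                          # expected info, log scale
    step <- score / pmax(info, 1e-12)
    step <- pmax(pmin(step, 2), -2)
    q <- q * exp(step)
    q[zero] <- zero_pseudo / rowSums(f)[zero]
    if (max(abs(step[!zero]), 0) < 1e-10) break
  }
  list(q = q, info = rowSums((f * q) / (1 + alpha * f * q)))
}

# Method-of-moments dispersion per position with a 1/mu trend fitted by
# robust regression; individual estimates are shrunk halfway to the
# trend and floored. Var(K/f) = q * E(1/f) + alpha * q^2 under the model.
estimate_dispersion <- function(KA, KB, fA, fB, floor = 1e-8) {
  Y <- cbind(KA / fA, KB / fB)
  nA <- ncol(KA); nB <- ncol(KB)
  mA <- rowMeans(KA / fA); mB <- rowMeans(KB / fB)
  resid2 <- rowSums((KA / fA - mA)^2) + rowSums((KB / fB - mB)^2)
  dfree <- max(nA + nB - 2L, 1L)
  v <- resid2 / dfree
  m <- rowMeans(Y)
  inv_f <- rowMeans(cbind(1 / fA, 1 / fB))
  raw <- (v - m * inv_f) / pmax(m, 1e-8)^2
  ok <- is.finite(raw) & m > 0
  trend <- rep(floor, length(raw))
  if (sum(ok) >= 10) {
    fit <- tryCatch(
      MASS::rlm(raw[ok] ~ I(1 / m[ok]), maxit = 50),
      error = function(e) lm(raw[ok] ~ I(1 / m[ok])))
    co <- coef(fit)
    trend <- pmax(co[1] + co[2] / pmax(m, 1e-8), floor)
  }
  pmax((pmax(raw, floor) + trend) / 2, floor)
}

#' Two-group negative-binomial Wald test with per-observation factors
#'
#' Per-position test of differential occupancy between two conditions.
#' The mean model is `mu = factor * q(condition)`; `q_A` and `q_B` are
#' estimated by maximising the NB likelihood at a per-position
#' dispersion obtained by method of moments on factor-normalised
#' counts, shrunk halfway towards a robustly fitted `a0 + a1/mu` trend
#' and floored. The Wald statistic is the log fold change divided by
#' its asymptotic standard error from the expected Fisher information;
#' in the dispersion-to-zero limit it reduces to the Poisson Wald
#' statistic.
#'
#' @param counts_A,counts_B integer matrices, positions by replicates.
#' @param factors_A,factors_B positive matrices of the same shapes
#'   (recycled from vectors if needed).
#' @param dispersion `"moment"` (default: estimate as described) or
#'   `"fixed"`.
#' @param alpha fixed per-position dispersion (scalar or vector) when
#'   `dispersion = "fixed"`.
#' @param cfg a [differential_config()] (supplies floor and zero
#'   policy).
#' @return data.frame with `base_mean` (mean normalised count),
#'   `log2_fold_change` (B vs A), `se_log2fc`, `wald_stat`, `wald_p`
#'   and `dispersion`.
#' @export
nb_wald_test <- function(counts_A, counts_B, factors_A = 1, factors_B = 1,
                         dispersion = c("moment", "fixed"), alpha = NULL,
                         cfg = differential_config()) {
  dispersion <- match.arg(dispersion)
  KA <- as.matrix(counts_A); KB <- as.matrix(counts_B)
  if (nrow(KA) != nrow(KB)) stop("count matrices disagree on positions")
  if (any(rowSums(KA) + rowSums(KB) == 0))
    stop("all-zero position in the count matrix; drop null counts first")
  expand <- function(f, K) {
    if (is.matrix(f)) f else matrix(f, nrow(K), ncol(K), byrow = is.null(dim(f)) &&
                                      length(f) == ncol(K))
  }
  fA <- expand(factors_A, KA); fB <- expand(factors_B, KB)
  if (any(fA <= 0) || any(fB <= 0)) stop("normalisation factors must be > 0")
  a <- if (dispersion == "fixed") {
    if (is.null(alpha)) stop("alpha required for fixed dispersion")
    pmax(rep_len(alpha, nrow(KA)), cfg$dispersion_floor)
  } else estimate_dispersion(KA, KB, fA, fB, floor = cfg$dispersion_floor)
  fitA <- nb_fit_q(KA, fA, a, cfg$zero_pseudo)
  fitB <- nb_fit_q(KB, fB, a, cfg$zero_pseudo)
  lfc_ln <- log(fitB$q) - log(fitA$q)
  se_ln <- sqrt(1 / pmax(fitA$info, 1e-12) + 1 / pmax(fitB$info, 1e-12))
  z <- lfc_ln / se_ln
  data.frame(base_mean = rowMeans(cbind(KA / fA, KB / fB)),
             log2_fold_change = lfc_ln / log(2),
             se_log2fc = se_ln / log(2),
             wald_stat = z,
             wald_p = 2 * pnorm(-abs(z)),
             dispersion = a)
}

#' Local false discovery rate from a p-value mixture
#'
#' Two-component mixture estimator: the null proportion `eta0` is
#' estimated from the upper tail of the p-value distribution (Storey,
#' `lambda = 0.5` by default) and the p-value density by the Grenander
#' estimator — the nonincreasing density given by the left derivative
#' of the least concave majorant of the empirical CDF. The local FDR at
#' p is `min(1, eta0 / f(p))`, nondecreasing in p by construction.
#'
#' @param p numeric vector of p-values (at least `min_n` of them for a
#'   stable density estimate).
#' @param lambda tail cut-off for the null-proportion estimate.
#' @param min_n minimum number of p-values required (default 100).
#' @return numeric vector of local FDR values in \[0, 1\], in the input
#'   order, with attribute `"eta0"`.
#' @export
local_fdr <- function(p, lambda = 0.5, min_n = 100L) {
  p <- as.numeric(p)
  if (length(p) < min_n)
    stop("need at least ", min_n,
         " p-values for local FDR estimation; pool more positions")
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  n <- length(p)
  eta0 <- min(1, mean(p >= lambda) / (1 - lambda))
  sp <- sort(unique(p))
  x <- c(0, sp, 1)
  Fx <- c(0, ecdf(p)(sp), 1)
  dx <- diff(x)
  dF <- diff(Fx)
  keep <- dx > 0
  dx <- dx[keep]; dF <- dF[keep]
  slopes <- dF / dx
  # least concave majorant via pool-adjacent-violators (nonincreasing slopes)
  ns <- length(slopes)
  val <- numeric(ns); wt <- numeric(ns); span <- integer(ns); m <- 0L
  for (i in seq_len(ns)) {
    m <- m + 1L
    val[m] <- slopes[i]; wt[m] <- dx[i]; span[m] <- 1L
    while (m > 1L && val[m - 1L] < val[m]) {
      pooled <- (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) /
        (wt[m - 1L] + wt[m])
      wt[m - 1L] <- wt[m - 1L] + wt[m]
      span[m - 1L] <- span[m - 1L] + span[m]
      val[m - 1L] <- pooled
      m <- m - 1L
    }
  }
  fhat_seg <- rep(val[seq_len(m)], times = span[seq_len(m)])
  # density at each p: slope of the interval (x_{i-1}, x_i] containing it
  knots <- cumsum(c(0, dx))  # all knot positions, 0 .. 1
  idx <- findInterval(p, knots, left.open = TRUE)
  idx <- pmin(pmax(idx, 1L), length(fhat_seg))
  fhat <- fhat_seg[idx]
  lfdr <- pmin(1, eta0 / pmax(fhat, 1e-12))
  attr(lfdr, "eta0") <- eta0
  lfdr
}

#' Apply the significance thresholds
#'
#' Flags positions with `|log2 fold change| > lfc_threshold` and
#' `local FDR < lfdr_threshold` (strict inequalities on both sides,
#' matching the calibration that a replicate self-comparison yields no
#' calls).
#'
#' @param results data.frame with columns `log2_fold_change` and
#'   `lfdr`.
#' @param cfg a [differential_config()].
#' @return `results` with a logical `significant` column added.
#' @export
call_significant <- function(results, cfg = differential_config()) {
  stopifnot(all(c("log2_fold_change", "lfdr") %in% names(results)))
  results$significant <- abs(results$log2_fold_change) > cfg$lfc_threshold &
    results$lfdr < cfg$lfdr_threshold
  results
}

#' Huber M-estimator of location
#'
#' Iteratively reweighted robust mean with tuning constant `k` on the
#' MAD scale: observations within `k * MAD` of the current estimate get
#' full weight, more distant ones are downweighted proportionally. With
#' no downweighted value the estimate equals the arithmetic mean; with
#' heavy outliers it moves towards the median.
#'
#' @param x numeric vector (non-empty).
#' @param k tuning constant (default 1.345).
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return The location estimate (scalar).
#' @export
huber_mean <- function(x, k = 1.345, tol = 1e-9, max_iter = 200L) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty input")
  s <- mad(x)
  if (s == 0) return(median(x))
  mu <- median(x)
  for (i in seq_len(max_iter)) {
    r <- x - mu
    w <- pmin(1, k * s / pmax(abs(r), 1e-300))
    mu_new <- sum(w * x) / sum(w)
    if (abs(mu_new - mu) < tol * max(1, abs(mu))) return(mu_new)
    mu <- mu_new
  }
  mu
}

#' Per-position differential occupancy between two conditions
#'
#' End-to-end wrapper: derives input-based normalisation factors from
#' the count matrix, runs the NB Wald test between the two conditions'
#' IP samples, estimates local FDRs from the p-values, and applies the
#' significance thresholds. `base_mean` is the robust (Huber) mean of
#' the factor-normalised counts across IP samples.
#'
#' @param pcm a `position_count_matrix` with IP and input samples for
#'   exactly two conditions.
#' @param condition_a,condition_b condition labels (B is tested against
#'   A; positive log2 fold change means higher in B).
#' @param cfg a [differential_config()].
#' @return data.frame: position, base_mean, log2_fold_change, wald_p,
#'   lfdr, significant.
#' @export
differential_occupancy <- function(pcm, condition_a, condition_b,
                                   cfg = differential_config()) {
  stopifnot(inherits(pcm, "position_count_matrix"))
  sm <- pcm$samples
  f <- normalization_factors(pcm)
  a_ids <- sm$sample_id[!sm$is_input & sm$condition == condition_a]
  b_ids <- sm$sample_id[!sm$is_input & sm$condition == condition_b]
  if (!length(a_ids) || !length(b_ids))
    stop("both conditions need at least one IP sample")
  KA <- pcm$counts[, a_ids, drop = FALSE]
  KB <- pcm$counts[, b_ids, drop = FALSE]
  keep <- rowSums(KA) + rowSums(KB) > 0
  res <- nb_wald_test(KA[keep, , drop = FALSE], KB[keep, , drop = FALSE],
                      f[keep, a_ids, drop = FALSE],
                      f[keep, b_ids, drop = FALSE], cfg = cfg)
  norm <- cbind(KA[keep, , drop = FALSE] / f[keep, a_ids, drop = FALSE],
                KB[keep, , drop = FALSE] / f[keep, b_ids, drop = FALSE])
  out <- data.frame(position = pcm$positions[keep],
                    base_mean = apply(norm, 1, huber_mean),
                    log2_fold_change = res$log2_fold_change,
                    wald_p = res$wald_p)
  out$lfdr <- as.numeric(local_fdr(out$wald_p))
  call_significant(out, cfg)
}
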