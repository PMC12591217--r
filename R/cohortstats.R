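#' Synthetic diagnostic cohort specification
#'
#' Describes a three-group study (Alzheimer's disease, mild cognitive
#' impairment, healthy controls) with per-group analyte concentration
#' distributions. The default emulates the clinical arm of the platform's
#' validation: 20 AD, 10 MCI and 30 CON subjects, log-normal plasma
#' concentrations of membrane-bound Abeta42 rising across CON < MCI < AD,
#' with the group separations on the log scale calibrated so the binormal
#' AUC is 0.94 for AD vs CON and 0.82 for MCI vs CON.
#'
#' @param n named integer vector of group sizes (each >= 1).
#' @param location per-group location: `meanlog` for `dist = "lognormal"`,
#'   mean for `dist = "normal"`.
#' @param scale per-group scale (`sdlog` or sd), > 0.
#' @param dist `"lognormal"` (non-negative, right-skewed biomarker levels)
#'   or `"normal"` (latent scores, used for binormal checks).
#' @param readout_noise_sd additive sensor-unit noise on the simulated
#'   readout (applied in the readout pipeline only).
#' @param seed default RNG seed recorded with every result.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(AD = 20, MCI = 10, CON = 30),
                        location = c(AD = log(5) + stats::qnorm(0.94) * sqrt(2) * 0.5,
                                     MCI = log(5) + stats::qnorm(0.82) * sqrt(2) * 0.5,
                                     CON = log(5)),
                        scale = c(AD = 0.5, MCI = 0.5, CON = 0.5),
                        dist = c("lognormal", "normal"),
                        readout_noise_sd = 5, seed = 1) {
  dist <- match.arg(dist)
  if (is.null(names(n)) || any(n < 1))
    stop("argument error: group sizes must be named and >= 1", call. = FALSE)
  groups <- names(n)
  if (!all(groups %in% names(location)) || !all(groups %in% names(scale)))
    stop("argument error: location and scale must cover every group in n",
         call. = FALSE)
  if (any(scale <= 0))
    stop("argument error: scales must be > 0", call. = FALSE)
  structure(list(n = n, location = location[groups], scale = scale[groups],
                 dist = dist, readout_noise_sd = readout_noise_sd,
                 seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s; %s concentrations\n",
              paste(sprintf("%s = %d", names(x$n), x$n), collapse = ", "),
              x$dist))
  invisible(x)
}

#' Simulate a cohort through the assay + readout pipeline
#'
#' Draws one concentration per subject from the group distribution, then
#' scores each subject. With `pipeline = "readout"` the concentration is
#' pushed through the noiseless assay dose-response ([assay_response()]) and
#' the Beer-Lambert sensor model (`baseline * 10^(-A)`), plus Gaussian
#' sensor noise — so higher analyte levels give *lower* readout values, and
#' disease is flagged by low scores. With `pipeline = "identity"` the score
#' is the negated latent value (used to verify binormal AUC arithmetic
#' without the nonlinear chain).
#'
#' @param spec a [cohort_spec()].
#' @param assay an [assay_params()] for the dose-response.
#' @param baseline drift-free sensor intensity (sensor units).
#' @param pipeline `"readout"` or `"identity"`.
#' @param seed RNG seed; defaults to the spec's.
#' @return An object of class `cohort_result`: list with `subjects`
#'   (data frame `subject`, `group`, `concentration`, `readout`), `tests`
#'   (pairwise rank tests), `roc` (AD vs CON, low readout = disease),
#'   `auc`, `cutoff`, `seed`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), assay = assay_params(),
                            baseline = 1500,
                            pipeline = c("readout", "identity"),
                            seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  pipeline <- match.arg(pipeline)
  set.seed(seed)
  groups <- rep(names(spec$n), spec$n)
  conc <- numeric(length(groups))
  for (g in names(spec$n)) {
    idx <- groups == g
    conc[idx] <- if (spec$dist == "lognormal")
      stats::rlnorm(sum(idx), spec$location[[g]], spec$scale[[g]])
    else
      stats::rnorm(sum(idx), spec$location[[g]], spec$scale[[g]])
  }
  readout <- if (pipeline == "readout") {
    if (spec$dist == "normal") conc <- pmax(conc, 0)
    mu <- baseline * 10^(-assay_response(conc, assay))
    if (spec$readout_noise_sd > 0)
      mu + stats::rnorm(length(mu), 0, spec$readout_noise_sd)
    else mu
  } else {
    -conc
  }
  subjects <- data.frame(subject = seq_along(groups), group = groups,
                         concentration = conc, readout = readout)
  pairs <- list(c("AD", "CON"), c("MCI", "CON"), c("AD", "MCI"))
  pairs <- Filter(function(p) all(p %in% names(spec$n)), pairs)
  tests <- lapply(pairs, function(p) {
    mw <- mann_whitney_u(readout[groups == p[1]], readout[groups == p[2]])
    data.frame(comparison = paste(p, collapse = " vs "),
               U = mw$U, p_value = mw$p_value, method = mw$method)
  })
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  roc <- NULL; cutoff <- NULL; auc <- NA_real_
  if (all(c("AD", "CON") %in% names(spec$n))) {
    sel <- groups %in% c("AD", "CON")
    roc <- empirical_roc(readout[sel], groups[sel] == "AD",
                         direction = "low")
    auc <- roc$auc
    cutoff <- choose_cutoff(roc)
  }
  structure(list(subjects = subjects, tests = tests, roc = roc, auc = auc,
                 cutoff = cutoff, seed = seed, pipeline = pipeline),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects (seed %d)\n",
              nrow(x$subjects), x$seed))
  if (!is.null(x$tests)) print(x$tests, row.names = FALSE)
  if (!is.na(x$auc))
    cat(sprintf("  AD vs CON AUC = %.3f; cutoff <= %.4g: sens %.2f, spec %.2f\n",
                x$auc, x$cutoff$cutoff, x$cutoff$sensitivity,
                x$cutoff$specificity))
  invisible(x)
}

#' Mann-Whitney U test (rank-sum), two-sided
#'
#' U is computed by midrank summation (ties get average ranks); the reported
#' `U` is the smaller of the two one-sided statistics. The p-value is exact
#' — full enumeration of all `choose(n1 + n2, n1)` group labelings — when
#' the smaller sample has at most 8 observations and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` (min convention), `U_x`, `U_y`, `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("argument error: both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(c(x, y))))
    stop("argument error: samples must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_y <- n1 * n2 - u_x
  ties <- table(r)
  has_ties <- any(ties > 1)
  mu <- n1 * n2 / 2
  if (min(n1, n2) <= 8 && !has_ties) {
    u_all <- u_enumerate(n1, n2)
    p <- mean(abs(u_all - mu) >= abs(u_x - mu) - 1e-9)
    method <- "exact"
  } else {
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u_x - mu - sign(u_x - mu) * 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = min(u_x, u_y), U_x = u_x, U_y = u_y, p_value = p, method = method)
}

# U statistic for every assignment of ranks 1..(n1+n2) to the first sample
u_enumerate <- function(n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  colSums(combos) - n1 * (n1 + 1) / 2
}

#' Empirical ROC curve and AUC
#'
#' Threshold sweep over the unique scores. `direction = "low"` declares that
#' low scores indicate disease (a subject is called positive when its score
#' is at or below the cutoff), matching an assay whose readout falls as the
#' biomarker rises; `"high"` is the reverse. The trapezoid AUC satisfies the
#' rank identity `AUC = U / (n1 * n2)` (midrank ties counted half).
#'
#' @param scores numeric scores.
#' @param labels logical (or coercible): `TRUE` = diseased/positive class.
#' @param direction `"low"` or `"high"`.
#' @return An object of class `roc_result`: list with `points` (data frame
#'   `threshold`, `tpr`, `fpr`), `auc`, `direction`, `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels) ||
      any(!is.finite(scores)))
    stop("argument error: scores and labels must be finite, same length",
         call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("argument error: both classes must be present", call. = FALSE)
  # cumulative counts over sorted unique scores: O(n log n)
  o <- order(scores, decreasing = (direction == "high"))
  s <- scores[o]; l <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)   # last index of each unique score
  thr <- s[last]
  tpr <- cumsum(l)[last] / n_pos
  fpr <- cumsum(!l)[last] / n_neg
  pts <- data.frame(threshold = c(if (direction == "low") -Inf else Inf,
                                  thr),
                    tpr = c(0, tpr), fpr = c(0, fpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, direction = direction,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive, %d negative, direction: %s scores = disease)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Choose a diagnostic cutoff from an ROC curve
#'
#' Default criterion is Youden's J (sensitivity + specificity - 1),
#' maximised over all thresholds; ties break toward higher specificity.
#'
#' @param roc a `roc_result`.
#' @param criterion currently `"youden"`.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
choose_cutoff <- function(roc, criterion = "youden") {
  stopifnot(inherits(roc, "roc_result"))
  criterion <- match.arg(criterion)
  pts <- roc$points[is.finite(roc$points$threshold), ]
  if (nrow(pts) < 1)
    stop("argument error: degenerate ROC curve", call. = FALSE)
  j <- pts$tpr - pts$fpr
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  best <- cand[which.min(pts$fpr[cand])]  # ties -> higher specificity
  list(cutoff = pts$threshold[best], sensitivity = pts$tpr[best],
       specificity = 1 - pts$fpr[best], j = j[best])
}
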