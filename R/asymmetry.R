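# Developmental-stability workflow: signed left/right differences, screens
# for antisymmetry and directional asymmetry, the balanced two-way mixed
# ANOVA, and the FA index suite with measurement-error partitioning.

#' Per-individual signed side differences for one trait-by-sex cell
#'
#' Computes d_i = mean(R replicates) - mean(L replicates) for every balanced
#' individual of the requested trait and sex. Individuals lacking exactly M
#' replicates on both sides are excluded and counted.
#'
#' @param table A \code{bilateral_measurements} data.frame.
#' @param trait,sex Cell selectors.
#' @return A list of class \code{signed_differences}: \code{trait},
#'   \code{sex}, \code{d} (named numeric), \code{n}, \code{mean}, \code{se}
#'   (SD/sqrt(n)), \code{n_excluded}.
#' @export
signed_differences <- function(table, trait, sex) {
  sub <- table[table$trait == trait & table$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0)
    stopf("no measurements for trait '%s', sex '%s'", trait, sex)
  M <- attr(table, "replicate_count") %||% max(sub$replicate)
  ids <- unique(sub$individual_id)
  per_side <- function(g) {
    nL <- sum(g$side == "L"); nR <- sum(g$side == "R")
    if (nL != M || nR != M || anyDuplicated(g[c("side", "replicate")]) > 0)
      return(NA_real_)
    mean(g$value[g$side == "R"]) - mean(g$value[g$side == "L"])
  }
  d <- vapply(split(sub, factor(sub$individual_id, levels = ids)), per_side,
              numeric(1))
  n_excluded <- sum(is.na(d))
  d <- d[!is.na(d)]
  if (length(d) < 3)
    stopf("trait '%s', sex '%s': fewer than 3 balanced individuals (%d)",
          trait, sex, length(d))
  if (n_excluded > 0)
    log_msg("signed_differences(%s, %s): excluded %d unbalanced individual(s)",
            trait, sex, n_excluded)
  n <- length(d)
  structure(list(trait = trait, sex = sex, d = d, n = n,
                 mean = mean(d), se = sd(d) / sqrt(n),
                 n_excluded = n_excluded),
            class = "signed_differences")
}

diff_values <- function(diffs) {
  if (inherits(diffs, "signed_differences")) diffs$d
  else if (is.numeric(diffs)) diffs
  else stopf("expected a signed_differences object or a numeric vector")
}

#' Antisymmetry screen: Shapiro-Wilk normality of signed differences
#'
#' Fluctuating asymmetry implies normally distributed R - L; a bimodal
#' (antisymmetric) distribution is rejected by this test. Normality
#' (p > alpha) therefore rules antisymmetry out.
#'
#' @param diffs A \code{\link{signed_differences}} object or numeric vector.
#' @param alpha Significance level (recorded, not used in the statistic).
#' @return A list with \code{W}, \code{p}, \code{n} and \code{alpha}.
#' @export
screen_antisymmetry <- function(diffs, alpha = 0.05) {
  d <- diff_values(diffs)
  if (length(d) < 3 || length(d) > 5000)
    stopf("Shapiro-Wilk screen requires 3 <= n <= 5000 (n = %d)", length(d))
  if (sd(d) == 0)
    stopf("signed differences are constant; normality screen undefined")
  sw <- shapiro.test(d)
  list(W = unname(sw$statistic), p = sw$p.value, n = length(d), alpha = alpha)
}

#' Directional-asymmetry screen: one-sample t of mean(R - L) against zero
#'
#' A normal R - L distribution with non-zero mean indicates directional
#' asymmetry; the two-sided one-sample t-test (df = n - 1) checks the mean.
#'
#' @param diffs A \code{\link{signed_differences}} object or numeric vector.
#' @param alpha Significance level (recorded).
#' @param alternative Passed to \code{\link[stats]{t.test}}; two-sided by
#'   default.
#' @return A list with \code{t}, \code{p}, \code{df}, \code{n}, \code{alpha}.
#' @export
screen_directional <- function(diffs, alpha = 0.05,
                               alternative = "two.sided") {
  d <- diff_values(diffs)
  if (length(d) < 2)
    stopf("directional screen requires n >= 2")
  if (sd(d) == 0)
    stopf("signed differences have zero variance; t-test undefined")
  tt <- t.test(d, mu = 0, alternative = alternative)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(d), alpha = alpha)
}

#' Two-way mixed-model ANOVA for replicated bilateral measurements
#'
#' Balanced side (fixed) x individual (random) ANOVA with M replicates per
#' cell, the design under which the side-by-individual interaction isolates
#' fluctuating asymmetry and the residual stratum isolates replicate
#' measurement error. Sums of squares are the closed-form balanced
#' decomposition:
#' \deqn{SS_{side} = nM \sum_s (\bar y_s - \bar y)^2, \quad
#'       SS_{ind} = 2M \sum_i (\bar y_i - \bar y)^2,}
#' \deqn{SS_{S \times I} = M \sum_{s,i} (\bar y_{si} - \bar y_s - \bar y_i
#'       + \bar y)^2, \quad SS_{err} = \sum (y_{sim} - \bar y_{si})^2.}
#' Following mixed-model convention, F for side and individual uses the
#' interaction mean square as denominator, F for the interaction uses the
#' error mean square; the denominators are recorded so alternates can be
#' audited.
#'
#' @param table A \code{bilateral_measurements} data.frame.
#' @param trait,sex Cell selectors.
#' @return A list of class \code{fa_anova} with data.frame \code{table}
#'   (term, df, ss, ms, f, p, denominator) plus \code{n}, \code{M},
#'   \code{grand_mean}.
#' @export
two_way_mixed_anova <- function(table, trait, sex) {
  sub <- table[table$trait == trait & table$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0)
    stopf("no measurements for trait '%s', sex '%s'", trait, sex)
  M <- attr(table, "replicate_count") %||% max(sub$replicate)
  if (M < 2)
    stopf("ANOVA requires M >= 2 replicates; no error stratum with M = %d", M)
  ids <- sort(unique(sub$individual_id))
  n <- length(ids)
  counts <- table(factor(sub$individual_id, levels = ids), sub$side)
  if (!all(counts == M) || ncol(counts) != 2 || nrow(sub) != 2 * n * M)
    stopf("trait '%s', sex '%s': unbalanced design; filter to balanced individuals first",
          trait, sex)

  y <- sub$value
  side <- sub$side
  id <- factor(sub$individual_id, levels = ids)
  gm <- mean(y)
  m_side <- tapply(y, side, mean)
  m_id <- tapply(y, id, mean)
  m_cell <- tapply(y, list(side, id), mean)

  ss_side <- n * M * sum((m_side - gm)^2)
  ss_ind <- 2 * M * sum((m_id - gm)^2)
  inter <- sweep(sweep(m_cell, 1, m_side), 2, m_id) + gm
  ss_int <- M * sum(inter^2)
  ss_err <- sum((y - m_cell[cbind(side, as.character(id))])^2)

  df <- c(side = 1, individual = n - 1, interaction = n - 1,
          error = 2 * n * (M - 1))
  ss <- c(ss_side, ss_ind, ss_int, ss_err)
  ms <- ss / df
  f <- c(ms[1] / ms[3], ms[2] / ms[3], ms[3] / ms[4], NA)
  p <- c(pf(f[1], df[1], df[3], lower.tail = FALSE),
         pf(f[2], df[2], df[3], lower.tail = FALSE),
         pf(f[3], df[3], df[4], lower.tail = FALSE), NA)
  out <- data.frame(
    term = c("side", "individual", "side:individual", "error"),
    df = unname(df), ss = ss, ms = ms, f = f, p = p,
    denominator = c("side:individual", "side:individual", "error", NA),
    stringsAsFactors = FALSE
  )
  structure(list(table = out, n = n, M = M, trait = trait, sex = sex,
                 grand_mean = gm),
            class = "fa_anova")
}

#' @export
print.fa_anova <- function(x, ...) {
  cat(sprintf("Two-way mixed ANOVA (side fixed, individual random): %s, %s\n",
              x$trait, x$sex))
  cat(sprintf("n = %d individuals, M = %d replicates/side\n", x$n, x$M))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' FA1: mean absolute signed difference
#'
#' The simplest asymmetry index, mean of |R - L|. It contains replicate
#' measurement error.
#'
#' @param diffs A \code{\link{signed_differences}} object or numeric vector.
#' @return Non-negative scalar in trait units.
#' @export
fa1 <- function(diffs) {
  d <- diff_values(diffs)
  if (length(d) < 1) stopf("FA1 requires n >= 1")
  mean(abs(d))
}

#' FA4a: 0.798 times the SD of signed differences
#'
#' For a centred normal d the half-normal mean is sigma * sqrt(2/pi) =
#' 0.798 sigma, so FA4a estimates the mean absolute asymmetry from the
#' (n - 1)-denominator sample SD. Like FA1 it includes measurement error.
#'
#' @param diffs A \code{\link{signed_differences}} object or numeric vector.
#' @return Non-negative scalar in trait units.
#' @export
fa4a <- function(diffs) {
  d <- diff_values(diffs)
  if (length(d) < 2) stopf("FA4a requires n >= 2")
  0.798 * sqrt(var(d))
}

#' FA10a: measurement-error-corrected asymmetry from ANOVA mean squares
#'
#' Partitions replicate measurement error out of the asymmetry signal. The
#' side-by-individual interaction variance component is estimated from the
#' balanced two-way ANOVA as
#' \deqn{\hat\sigma_i^2 = \max(0, (MS_{S\times I} - MS_{err}) / M),}
#' the standard M-replicate variance-component estimator, and
#' FA10a = 0.798 sqrt(2 sigma_i^2) returns to the mean-|R - L| scale (under
#' the symmetric side split, var(R - L) = 2 sigma_i^2).
#' \code{use_printed_formula = TRUE} drops the divisor M
#' (sigma_i^2 = MS_SxI - MS_err), a variant that appears in some published
#' accounts; the divisor form is the default because it is the estimator
#' whose target is the interaction variance component.
#'
#' @param ms_interaction Mean square of the side-by-individual interaction.
#' @param ms_error Residual (replicate) mean square.
#' @param M Number of replicate measurements per side.
#' @param use_printed_formula If \code{TRUE}, omit the divisor M.
#' @return List with \code{sigma_i_sq} and \code{fa10a}; a negative variance
#'   estimate is clamped to zero with a warning.
#' @export
fa10a <- function(ms_interaction, ms_error, M, use_printed_formula = FALSE) {
  if (!is_number(ms_interaction) || ms_interaction < 0)
    stopf("ms_interaction must be a non-negative number")
  if (!is_number(ms_error) || ms_error < 0)
    stopf("ms_error must be a non-negative number")
  if (!is_count(M, min = 2)) stopf("M must be an integer >= 2")
  sigma_i_sq <- if (use_printed_formula) ms_interaction - ms_error
                else (ms_interaction - ms_error) / M
  if (sigma_i_sq < 0) {
    warnf("interaction MS below error MS; variance component clamped to 0")
    sigma_i_sq <- 0
  }
  list(sigma_i_sq = sigma_i_sq, fa10a = 0.798 * sqrt(2 * sigma_i_sq))
}

#' ME3: replicate measurement error as a percentage of the interaction MS
#'
#' 100 * MS_error / MS_SxI: the mean squared difference between repeat
#' measurements relative to the side-by-individual signal it contaminates.
#'
#' @param ms_error Residual (replicate) mean square.
#' @param ms_interaction Interaction mean square (> 0).
#' @return Percentage (>= 0; <= 100 whenever MS_SxI >= MS_error).
#' @export
me3 <- function(ms_error, ms_interaction) {
  if (!is_number(ms_interaction) || ms_interaction <= 0)
    stopf("ms_interaction must be > 0")
  if (!is_number(ms_error) || ms_error < 0)
    stopf("ms_error must be >= 0")
  100 * ms_error / ms_interaction
}

# Verdict is a pure function of the two screen p-values and alpha; a
# zero-variance cell is flagged as degenerate rather than classified.
asymmetry_verdict <- function(p_w, p_t, alpha, degenerate = FALSE) {
  if (degenerate) return("degenerate-zero-variance")
  if (p_w <= alpha) return("antisymmetry-suspected")
  if (p_t <= alpha) return("directional-asymmetry-suspected")
  "fluctuating-asymmetry-compatible"
}

#' Full asymmetry report per trait-by-sex cell
#'
#' Runs, for every trait-by-sex cell present in the table, the antisymmetry
#' and directional screens, the two-way mixed ANOVA and the FA index suite,
#' and classifies each cell. A cell whose analysis fails (too few balanced
#' individuals, zero variance, ...) is reported with its error message; the
#' other cells still run. With \code{subsample_n} set, a seeded random subset
#' of balanced individuals of that size is analysed per cell, mirroring
#' designs that measure ~30 randomly chosen individuals per test; the default
#' uses all balanced individuals.
#'
#' @param table A \code{bilateral_measurements} data.frame.
#' @param alpha Significance level for the screens.
#' @param subsample_n Optional number of individuals per cell.
#' @param seed Seed for the subsample draw.
#' @return A data.frame of class \code{fa_report}: one row per cell with
#'   columns \code{sex}, \code{trait}, \code{n}, \code{mean_d}, \code{se_d},
#'   \code{W}, \code{p_W}, \code{t}, \code{p_t}, \code{ms_interaction},
#'   \code{ms_error}, \code{f_side}, \code{f_individual},
#'   \code{f_interaction} (with p-values), \code{fa1}, \code{fa4a},
#'   \code{sigma_i_sq}, \code{fa10a}, \code{me3}, \code{mean_size},
#'   \code{fa1_over_mean_pct}, \code{verdict} and \code{error}.
#' @export
fa_report <- function(table, alpha = 0.05, subsample_n = NULL, seed = NULL) {
  cells <- unique(as.data.frame(table)[c("sex", "trait")])
  cells <- cells[order(cells$sex, cells$trait), , drop = FALSE]
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    sx <- cells$sex[k]; tr <- cells$trait[k]
    rows[[k]] <- tryCatch(
      fa_cell(table, tr, sx, alpha, subsample_n, seed),
      error = function(e) {
        data.frame(sex = sx, trait = tr, n = NA_integer_,
                   mean_d = NA_real_, se_d = NA_real_,
                   W = NA_real_, p_W = NA_real_, t = NA_real_, p_t = NA_real_,
                   ms_interaction = NA_real_, ms_error = NA_real_,
                   f_side = NA_real_, p_side = NA_real_,
                   f_individual = NA_real_, p_individual = NA_real_,
                   f_interaction = NA_real_, p_interaction = NA_real_,
                   fa1 = NA_real_, fa4a = NA_real_, sigma_i_sq = NA_real_,
                   fa10a = NA_real_, me3 = NA_real_, mean_size = NA_real_,
                   fa1_over_mean_pct = NA_real_,
                   verdict = NA_character_, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      }
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fa_report", "data.frame")
  out
}

fa_cell <- function(table, trait, sex, alpha, subsample_n, seed) {
  sub <- table[table$trait == trait & table$sex == sex, , drop = FALSE]
  attr(sub, "replicate_count") <- attr(table, "replicate_count")
  M <- attr(table, "replicate_count") %||% max(sub$replicate)

  # restrict to balanced individuals (and optionally a seeded subsample)
  counts <- table(sub$individual_id, sub$side)
  balanced <- rownames(counts)[rowSums(counts == M) == 2]
  if (!is.null(subsample_n) && subsample_n < length(balanced)) {
    balanced <- with_seed(seed, sample(balanced, subsample_n))
  }
  sub <- sub[sub$individual_id %in% balanced, , drop = FALSE]
  attr(sub, "replicate_count") <- M

  diffs <- signed_differences(sub, trait, sex)
  degenerate <- sd(diffs$d) == 0
  if (degenerate) {
    sw <- list(W = NA_real_, p = NA_real_)
    tt <- list(t = NA_real_, p = NA_real_)
  } else {
    sw <- screen_antisymmetry(diffs, alpha)
    tt <- screen_directional(diffs, alpha)
  }
  an <- two_way_mixed_anova(sub, trait, sex)
  at <- an$table
  ms_int <- at$ms[at$term == "side:individual"]
  ms_err <- at$ms[at$term == "error"]
  idx10 <- fa10a(ms_int, ms_err, M)
  mean_size <- an$grand_mean
  v_fa1 <- fa1(diffs)

  data.frame(
    sex = sex, trait = trait, n = diffs$n,
    mean_d = diffs$mean, se_d = diffs$se,
    W = sw$W, p_W = sw$p, t = tt$t, p_t = tt$p,
    ms_interaction = ms_int, ms_error = ms_err,
    f_side = at$f[at$term == "side"], p_side = at$p[at$term == "side"],
    f_individual = at$f[at$term == "individual"],
    p_individual = at$p[at$term == "individual"],
    f_interaction = at$f[at$term == "side:individual"],
    p_interaction = at$p[at$term == "side:individual"],
    fa1 = v_fa1, fa4a = fa4a(diffs), sigma_i_sq = idx10$sigma_i_sq,
    fa10a = idx10$fa10a,
    me3 = if (ms_int > 0) me3(ms_err, ms_int) else NA_real_,
    mean_size = mean_size,
    fa1_over_mean_pct = 100 * v_fa1 / mean_size,
    verdict = asymmetry_verdict(sw$p, tt$p, alpha, degenerate),
    error = NA_character_,
    stringsAsFactors = FALSE
  )
}
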