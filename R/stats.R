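#' Mann-Whitney U test for two independent samples
#'
#' Rank-based two-sample location test. `exact` mode computes the full
#' permutation distribution of U over all assignments of the pooled values
#' to the two groups (a dynamic program over midranks, so ties are handled
#' exactly); `normal_approx` uses the normal approximation with continuity
#' and tie corrections. `auto` chooses exact when the smaller group has at
#' most 12 observations.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `U` (the statistic for `group_a`), `p` (two-sided)
#'   and `mode` actually used.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  na <- length(group_a)
  nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("input error: both groups must be non-empty")
  pooled <- c(group_a, group_b)
  rk <- rank(pooled) # midranks for ties
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "auto") {
    mode <- if (min(na, nb) <= 12L) "exact" else "normal_approx"
  }
  mu <- na * nb / 2
  if (mode == "exact") {
    # distribution of twice the rank sum of group A over all C(n, na)
    # subsets; 2 * midranks are integers
    w <- as.integer(round(2 * rk))
    p <- exact_ranksum_pvalue(w, na, w_obs = as.integer(round(2 * sum(rk[seq_len(na)]))))
  } else {
    n <- na + nb
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  list(U = u_obs, p = p, mode = mode)
}

# Two-sided exact p for the permutation distribution of the group-A rank
# sum. w: integer weights (2 * midranks) of the n pooled items; na: group-A
# size; w_obs: observed group-A weight sum. The distribution is symmetric
# about na * mean(w), so P(|W - mu| >= |w_obs - mu|) is the two-sided p.
exact_ranksum_pvalue <- function(w, na, w_obs) {
  n <- length(w)
  s_max <- sum(sort(w, decreasing = TRUE)[seq_len(na)])
  # counts[j + 1, s + 1] = number of size-j subsets with weight sum s
  counts <- matrix(0, nrow = na + 1L, ncol = s_max + 1L)
  counts[1L, 1L] <- 1
  for (i in seq_len(n)) {
    wi <- w[i]
    jmax <- min(i, na)
    for (j in jmax:1) {
      src <- counts[j, seq_len(s_max + 1L - wi)]
      counts[j + 1L, (wi + 1L):(s_max + 1L)] <-
        counts[j + 1L, (wi + 1L):(s_max + 1L)] + src
    }
  }
  dist <- counts[na + 1L, ]
  total <- sum(dist)
  sums <- 0:s_max
  mu <- na * mean(w)
  dev_obs <- abs(w_obs - mu)
  sum(dist[abs(sums - mu) >= dev_obs - 1e-9]) / total
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p by the conditional-probability criterion: with both margins
#' fixed, the p-value is the sum of hypergeometric probabilities of all
#' tables no more probable than the observed one (the construction used by
#' standard statistical packages).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("input error: table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("input error: counts must be non-negative integers")
  }
  a <- table[1, 1]
  r1 <- sum(table[1, ])
  r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  if (r1 + r2 == 0) stop("input error: empty table")
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Build the divergence-center contingency table
#'
#' Cross-tabulates divergence-center counts against region. `as_printed`
#' uses columns (center count, total point count) per region — the
#' construction that reproduces the study's printed Fisher p-values from
#' its printed counts. `conventional` uses the statistically standard
#' columns (center count, non-center count).
#'
#' @param points a `sample_point_set` whose records carry `is_center`, or a
#'   data.frame with columns `region` and `is_center`.
#' @param mode `"as_printed"` (default) or `"conventional"`.
#' @return 2x2 integer matrix, rows `bleb`/`nonbleb`.
#' @export
build_center_contingency <- function(points,
                                     mode = c("as_printed", "conventional")) {
  mode <- match.arg(mode)
  d <- if (inherits(points, "sample_point_set")) as.data.frame(points)
       else points
  if (!all(c("region", "is_center") %in% names(d))) {
    stop("points must carry region labels and is_center flags")
  }
  counts_for <- function(region) {
    sel <- d$region == region
    c(centers = sum(d$is_center[sel]), total = sum(sel))
  }
  b <- counts_for("bleb")
  nb <- counts_for("nonbleb")
  tab <- rbind(bleb = b, nonbleb = nb)
  if (mode == "conventional") {
    tab[, 2] <- tab[, 2] - tab[, 1]
    colnames(tab) <- c("centers", "non_centers")
  } else {
    colnames(tab) <- c("centers", "total")
  }
  storage.mode(tab) <- "integer"
  tab
}

#' Region-wise comparison report
#'
#' Summarises the multipoint measurements the way the study tabulates them:
#' per parameter (normalized pressure, normalized WSS, TAWSS, OSI) the
#' mean +/- SD in the bleb-formation and bleb-free groups with a two-sided
#' Mann-Whitney p, and for the divergence centers a contingency table with
#' a two-sided Fisher exact p — per case and pooled. SD is the sample SD
#' (n - 1); points with undefined (NA) OSI are excluded from the OSI row
#' with their count reported.
#'
#' @param points a `sample_point_set` with measurement records, or a
#'   data.frame with columns `region`, `is_center`, the parameter columns,
#'   and optionally `case`.
#' @param parameters character vector of record columns to compare.
#' @param contingency_mode passed to [build_center_contingency()].
#' @param mw_mode passed to [mann_whitney_u()].
#' @return An object of class `comparison_report`: list with data.frames
#'   `summary` (one row per case x parameter) and `centers` (one row per
#'   case), plus `n_excluded_osi`.
#' @export
summarize_comparison <- function(points,
                                 parameters = c("normalized_pressure",
                                                "normalized_wss",
                                                "tawss", "osi"),
                                 contingency_mode = c("as_printed",
                                                      "conventional"),
                                 mw_mode = "auto") {
  contingency_mode <- match.arg(contingency_mode)
  d <- if (inherits(points, "sample_point_set")) as.data.frame(points)
       else points
  if (!"case" %in% names(d)) d$case <- "case1"
  cases <- unique(d$case)
  scopes <- c(as.list(cases), list(cases))
  scope_names <- c(cases, "total")
  if (length(cases) == 1L) { scopes <- list(cases); scope_names <- cases }
  parameters <- intersect(parameters, names(d))
  n_excl_osi <- if ("osi" %in% parameters) sum(is.na(d$osi)) else 0L
  rows <- list()
  crows <- list()
  for (si in seq_along(scopes)) {
    ds <- d[d$case %in% scopes[[si]], , drop = FALSE]
    a <- ds[ds$region == "bleb", , drop = FALSE]
    b <- ds[ds$region == "nonbleb", , drop = FALSE]
    for (par in parameters) {
      va <- a[[par]][!is.na(a[[par]])]
      vb <- b[[par]][!is.na(b[[par]])]
      p <- if (length(va) > 0L && length(vb) > 0L) {
        mann_whitney_u(va, vb, mode = mw_mode)$p
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        case = scope_names[si], parameter = par,
        mean_bleb = if (length(va)) mean(va) else NA_real_,
        sd_bleb = if (length(va) >= 2L) stats::sd(va) else NA_real_,
        n_bleb = length(va),
        mean_nonbleb = if (length(vb)) mean(vb) else NA_real_,
        sd_nonbleb = if (length(vb) >= 2L) stats::sd(vb) else NA_real_,
        n_nonbleb = length(vb),
        p_value = p, test = "mann_whitney",
        significant = !is.na(p) & p < 0.05,
        stringsAsFactors = FALSE)
    }
    if ("is_center" %in% names(ds)) {
      tab <- build_center_contingency(ds, mode = contingency_mode)
      tab_printed <- build_center_contingency(ds, mode = "as_printed")
      fp <- fisher_exact_2x2(tab)
      crows[[length(crows) + 1L]] <- data.frame(
        case = scope_names[si],
        centers_bleb = tab_printed["bleb", "centers"],
        n_bleb = tab_printed["bleb", "total"],
        centers_nonbleb = tab_printed["nonbleb", "centers"],
        n_nonbleb = tab_printed["nonbleb", "total"],
        prevalence_bleb_pct =
          100 * tab_printed["bleb", "centers"] / tab_printed["bleb", "total"],
        prevalence_nonbleb_pct =
          100 * tab_printed["nonbleb", "centers"] /
          tab_printed["nonbleb", "total"],
        p_value = fp, test = "fisher_exact",
        contingency_mode = contingency_mode,
        significant = fp < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 centers = if (length(crows)) do.call(rbind, crows) else NULL,
                 n_excluded_osi = n_excl_osi),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Multipoint comparison: bleb-formation area vs area without\n\n")
  s <- x$summary
  for (cs in unique(s$case)) {
    ss <- s[s$case == cs, , drop = FALSE]
    cat(sprintf("%s (n_bleb = %d, n_nonbleb = %d)\n", cs,
                ss$n_bleb[1], ss$n_nonbleb[1]))
    for (i in seq_len(nrow(ss))) {
      cat(sprintf("  %-20s %8.4f +/- %-8.4f  vs %8.4f +/- %-8.4f  p = %s%s\n",
                  ss$parameter[i], ss$mean_bleb[i], ss$sd_bleb[i],
                  ss$mean_nonbleb[i], ss$sd_nonbleb[i],
                  stats::format.pval(ss$p_value[i], digits = 3),
                  ifelse(isTRUE(ss$significant[i]), " *", "")))
    }
    if (!is.null(x$centers)) {
      cc <- x$centers[x$centers$case == cs, , drop = FALSE]
      if (nrow(cc) == 1L) {
        cat(sprintf(
          "  %-20s %d (%.1f%%)          vs %d (%.1f%%)           p = %s%s\n",
          "divergence centers", cc$centers_bleb, cc$prevalence_bleb_pct,
          cc$centers_nonbleb, cc$prevalence_nonbleb_pct,
          stats::format.pval(cc$p_value, digits = 3),
          ifelse(isTRUE(cc$significant), " *", "")))
      }
    }
  }
  if (x$n_excluded_osi > 0L) {
    cat("\n", x$n_excluded_osi,
        "point(s) with undefined OSI excluded from the OSI row\n")
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `summary.csv`, `centers.csv` and `report.json` under `dir`.
#'
#' @param report a [summarize_comparison()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$centers)) {
    utils::write.csv(report$centers, file.path(dir, "centers.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(summary = report$summary, centers = report$centers,
         n_excluded_osi = report$n_excluded_osi),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
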