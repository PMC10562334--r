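#' Paired change scores
#'
#' Computes change = postoperative - preoperative for every numeric variable
#' of a long cohort table (one row per subject x timepoint).
#'
#' @param table data frame with columns `id`, `timepoint` (`"pre"`/`"post"`)
#'   and numeric metric/outcome columns.
#' @return data frame with one row per subject and the change per variable.
#' @export
change_scores <- function(table) {
  stopifnot(all(c("id", "timepoint") %in% names(table)))
  pre <- table[table$timepoint == "pre", , drop = FALSE]
  post <- table[table$timepoint == "post", , drop = FALSE]
  if (!setequal(pre$id, post$id) || anyDuplicated(pre$id) ||
      anyDuplicated(post$id))
    stopf("every subject must have exactly one pre and one post row")
  post <- post[match(pre$id, post$id), , drop = FALSE]
  num <- vapply(table, is.numeric, logical(1)) &
    !(names(table) %in% c("id", "timepoint"))
  out <- data.frame(id = pre$id, stringsAsFactors = FALSE)
  for (v in names(table)[num]) out[[v]] <- post[[v]] - pre[[v]]
  out
}

#' Median with interquartile range
#'
#' Median and 25th/75th percentiles using linear interpolation between order
#' statistics (R's default quantile convention, type 7).
#'
#' @param x numeric vector; `NA`s dropped.
#' @return named vector `c(median, iq25, iq75)`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stopf("median_iqr on empty input")
  q <- quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], iq25 = q[2], iq75 = q[3])
}

# exact null distribution of the signed-rank statistic over doubled midranks
# (dynamic programming over achievable doubled rank sums)
signed_rank_exact_p <- function(w, ranks2) {
  maxs <- sum(ranks2)
  f <- numeric(maxs + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(maxs + 1)] <- g[(r + 1):(maxs + 1)] + f[1:(maxs + 1 - r)]
    f <- g
  }
  f <- f / sum(f)
  s <- 0:maxs
  mu <- maxs / 2
  sum(f[abs(s - mu) >= abs(w - mu) - 1e-9])
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Paired-sample signed-rank test with the classical zero-handling
#' convention: zero differences are dropped, tied absolute differences get
#' average (mid) ranks. The null distribution is exact (full enumeration via
#' dynamic programming, ties included) up to `exact_max` non-zero
#' differences, and a tie-corrected normal approximation with continuity
#' correction above.
#'
#' @param diffs numeric vector of paired differences; `NA`s dropped.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with statistic `W` (sum of positive ranks), `n` (non-zero
#'   differences), two-sided `p`, and `method`.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 25) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("no nonzero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(2 * W, round(2 * r))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(W - mu) - 0.5) / sigma
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal-approximation"
  }
  list(W = W, n = n, p = min(p, 1), method = method)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties; rho is the Pearson
#' correlation of the ranks. The p-value is exact by full permutation for
#' n <= `exact_max` and uses the t approximation above. Pairs with a missing
#' value in either variable are dropped (pairwise deletion).
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_max largest n for which the permutation-exact p is used.
#' @return list with `rho`, `n`, two-sided `p`, and `method`.
#' @export
spearman_cor <- function(x, y, exact_max = 8) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("spearman needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_(n)
    rhos <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, n = n, p = min(p, 1), method = method)
}

# all permutations of 1..n, built by inserting n into each position of the
# permutations of 1..(n-1)
permutations_ <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1
  for (s in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[s, ], n, after = pos - 1)
      row <- row + 1
    }
  }
  out
}

#' Build the cohort statistics report
#'
#' Reproduces the reporting layout of paired pre/post surgical CFD studies:
#' per-metric pre/post/change medians with interquartile ranges and two-sided
#' Wilcoxon signed-rank p-values; Spearman correlations of the operated-region
#' wall shear force and heat transfer against the subjective and volumetric
#' measures, on the pooled table (pre + post rows) and on the change table;
#' and the pressure-loss correlations. Missing outcomes are dropped pairwise
#' and every cell reports its n.
#'
#' @param table long cohort table: columns `id`, `timepoint`, metric columns
#'   (`roi_force`, `roi_heat`, `out_force`, `out_heat`, `roi_volume`,
#'   `pressure_loss`) and outcomes (`vas`, `ghsi`, `v25`); extra columns are
#'   ignored.
#' @return a `stats_report`: list of data frames `changes` (medians + p),
#'   `pooled_cor`, `change_cor`, `pressure_cor`.
#' @export
build_report <- function(table) {
  metrics <- intersect(c("roi_force", "roi_heat", "out_force", "out_heat",
                         "pressure_loss"), names(table))
  outcomes <- intersect(c("vas", "ghsi", "v25", "roi_volume"), names(table))
  ch <- change_scores(table)

  fmt_mi <- function(x) {
    m <- median_iqr(x)
    sprintf("%.3g (%.3g to %.3g)", m[1], m[2], m[3])
  }
  changes <- do.call(rbind, lapply(metrics, function(v) {
    pre <- table[[v]][table$timepoint == "pre"]
    post <- table[[v]][table$timepoint == "post"]
    wt <- wilcoxon_signed_rank(ch[[v]])
    data.frame(metric = v,
               pre_median = fmt_mi(pre),
               post_median = fmt_mi(post),
               change_median = fmt_mi(ch[[v]]),
               p = wt$p, n = wt$n, stringsAsFactors = FALSE)
  }))

  cor_table <- function(df, xs, ys) {
    do.call(rbind, lapply(xs, function(vx) {
      do.call(rbind, lapply(ys, function(vy) {
        sc <- spearman_cor(df[[vx]], df[[vy]])
        data.frame(x = vx, y = vy, rho = sc$rho, p = sc$p, n = sc$n,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  cfd <- intersect(c("roi_force", "roi_heat"), names(table))
  pooled_cor <- cor_table(table, cfd, outcomes)
  change_cor <- cor_table(ch, cfd, intersect(outcomes, names(ch)))
  pressure_cor <- NULL
  if ("pressure_loss" %in% names(table)) {
    pc1 <- cor_table(table, "pressure_loss",
                     intersect(c("vas", "ghsi"), names(table)))
    pc1$analysis <- "pooled"
    pc2 <- cor_table(ch, "pressure_loss",
                     intersect(c("vas", "ghsi", "roi_force"), names(ch)))
    pc2$analysis <- "change"
    pressure_cor <- rbind(pc1, pc2)
  }
  structure(list(changes = changes, pooled_cor = pooled_cor,
                 change_cor = change_cor, pressure_cor = pressure_cor,
                 n_subjects = length(unique(table$id)),
                 n_pooled = nrow(table)),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("cohort statistics report: %d subjects (pooled n = %d)\n\n",
              x$n_subjects, x$n_pooled))
  cat("Pre/post changes (Wilcoxon signed-rank, two-sided):\n")
  print(x$changes, row.names = FALSE)
  cat("\nPooled Spearman correlations:\n")
  print(x$pooled_cor, row.names = FALSE)
  cat("\nChange-score Spearman correlations:\n")
  print(x$change_cor, row.names = FALSE)
  if (!is.null(x$pressure_cor)) {
    cat("\nPressure-loss correlations:\n")
    print(x$pressure_cor, row.names = FALSE)
  }
  invisible(x)
}

#' Render a statistics report as Markdown tables
#'
#' @param report a `stats_report`.
#' @param path optional output file.
#' @return the Markdown lines, invisibly if written to `path`.
#' @export
report_markdown <- function(report, path = NULL) {
  md_tbl <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r)
      paste0("| ", paste(vapply(r, function(v)
        ifelse(is.na(suppressWarnings(as.numeric(v))), as.character(v),
               format(as.numeric(v), digits = 3)), character(1)),
        collapse = " | "), " |"))
    c(hdr, sep, rows)
  }
  out <- c("## Pre/post changes", md_tbl(report$changes), "",
           "## Pooled correlations", md_tbl(report$pooled_cor), "",
           "## Change correlations", md_tbl(report$change_cor))
  if (!is.null(report$pressure_cor))
    out <- c(out, "", "## Pressure-loss correlations",
             md_tbl(report$pressure_cor))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
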