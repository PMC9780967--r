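# Statistical-significance-based feature selection (paired t-tests).

#' Paired-sample t-test on Pre vs Post feature values
#'
#' Two-sided Student's t-test on the paired differences `x_pre - x_post`.
#' Degenerate cases are handled explicitly: if every difference is zero the
#' test reports `t = 0, p = 1`; if the differences have zero variance but a
#' nonzero mean, `t` is signed infinite and `p = 0`, with `degenerate = TRUE`.
#'
#' @param x_pre,x_post Equal-length numeric vectors (n >= 2 after removing
#'   incomplete pairs).
#' @return `list(t, dof, p, n, degenerate)`.
#' @examples
#' paired_ttest(c(1, 2, 3), c(1, 2, 3))$p  # 1
#' @export
paired_ttest <- function(x_pre, x_post) {
  if (length(x_pre) != length(x_post)) {
    stop("paired test requires equal-length samples", call. = FALSE)
  }
  ok <- is.finite(x_pre) & is.finite(x_post)
  d <- x_pre[ok] - x_post[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, dof = n - 1L, p = 1, n = n, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, dof = n - 1L, p = 0, n = n,
                degenerate = TRUE))
  }
  ht <- t.test(d)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value, n = n, degenerate = FALSE)
}

#' Paired-t selection report over a feature table
#'
#' Runs one paired t-test per feature column, comparing the Pre- and
#' Post-levodopa populations, and flags the features significant at `alpha`.
#' Rows are paired index-wise within subject (the i-th usable stride of a
#' subject's Pre session against the i-th of its Post session), truncating to
#' the shorter session; `pairing = "subject_mean"` instead collapses each
#' subject to its feature means before pairing.
#'
#' @param table_pre,table_post Feature data.frames sharing the feature
#'   columns (e.g. from [session_features()] or [truth_feature_table()]).
#' @param features Feature columns to test; defaults to every muscular and
#'   cortical feature present in both tables.
#' @param alpha Significance level (default 0.05). No multiple-testing
#'   correction is applied by default; `bonferroni = TRUE` divides `alpha` by
#'   the number of tests.
#' @param pairing `"indexwise"` (default) or `"subject_mean"`.
#' @param bonferroni Apply a Bonferroni correction to the selection rule.
#' @return A `wo_selection` data.frame: one row per feature with
#'   `mean_pre`, `mean_post`, `t_statistic`, `dof`, `p_value`, `selected`;
#'   attributes `alpha`, `pairing_scheme`, `n_pairs`.
#' @export
build_selection_report <- function(table_pre, table_post, features = NULL,
                                   alpha = 0.05, pairing = c("indexwise", "subject_mean"),
                                   bonferroni = FALSE) {
  pairing <- match.arg(pairing)
  stopifnot_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (is.null(features)) {
    cand <- c(muscular_features(), cortical_features())
    features <- cand[cand %in% names(table_pre) & cand %in% names(table_post)]
  }
  if (!length(features)) stop("no shared feature columns to test", call. = FALSE)

  pair_up <- function(tab) {
    sid <- tab$subject_id %||% rep("all", nrow(tab))
    split(tab[features], sid)
  }
  pre_s <- pair_up(table_pre)
  post_s <- pair_up(table_post)
  subjects <- intersect(names(pre_s), names(post_s))
  if (!length(subjects)) stop("no subjects in common between conditions", call. = FALSE)

  x_pre <- x_post <- NULL
  for (s in subjects) {
    a <- pre_s[[s]]; b <- post_s[[s]]
    if (pairing == "subject_mean") {
      a <- as.data.frame(lapply(a, mean, na.rm = TRUE))
      b <- as.data.frame(lapply(b, mean, na.rm = TRUE))
    } else {
      m <- min(nrow(a), nrow(b))
      if (nrow(a) != nrow(b)) {
        warning(sprintf("subject %s: truncating to %d pairs", s, m), call. = FALSE)
      }
      a <- a[seq_len(m), , drop = FALSE]
      b <- b[seq_len(m), , drop = FALSE]
    }
    x_pre <- rbind(x_pre, a)
    x_post <- rbind(x_post, b)
  }

  alpha_eff <- if (bonferroni) alpha / length(features) else alpha
  rows <- lapply(features, function(f) {
    ht <- paired_ttest(x_pre[[f]], x_post[[f]])
    data.frame(feature = f,
               mean_pre = mean(x_pre[[f]], na.rm = TRUE),
               mean_post = mean(x_post[[f]], na.rm = TRUE),
               t_statistic = ht$t, dof = ht$dof, p_value = ht$p,
               selected = ht$p < alpha_eff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, alpha = alpha, bonferroni = bonferroni,
            pairing_scheme = pairing, n_pairs = nrow(x_pre),
            class = c("wo_selection", "data.frame"))
}

#' @export
print.wo_selection <- function(x, ...) {
  cat(sprintf("<wo_selection> %d features, %d pairs (%s pairing), alpha = %g\n",
              nrow(x), attr(x, "n_pairs"), attr(x, "pairing_scheme"),
              attr(x, "alpha")))
  df <- as.data.frame(x)
  df$mean_pre <- round_half_up(df$mean_pre, 2)
  df$mean_post <- round_half_up(df$mean_post, 2)
  df$p_value <- signif(df$p_value, 3)
  df$t_statistic <- round_half_up(df$t_statistic, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
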