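#' Hypothesis and error SSCP matrices for a one-way layout
#'
#' Decomposes the total sum-of-squares-and-cross-products about the grand
#' mean into a between-group (hypothesis, H) and within-group (error, E)
#' part for a set of response columns grouped by one column — the classical
#' one-way MANOVA decomposition. Additivity holds exactly:
#' `H + E` equals the total SSCP.
#'
#' @param table Data frame with the response and grouping columns.
#' @param responses Character vector of response column names (p >= 1).
#' @param grouping Name of the grouping column (>= 2 groups, every group
#'   with >= 2 observations).
#' @return An `sscp_pair`: list with `H`, `E` (p x p matrices), `df_h`
#'   (groups - 1), `df_e` (n - groups), `p` and `groups`.
#' @export
sscp <- function(table, responses = response_names(),
                 grouping = "varied_factor") {
  missing_cols <- setdiff(c(responses, grouping), names(table))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- as.matrix(table[responses])
  grp <- as.factor(table[[grouping]])
  sizes <- table(grp)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs at least 2 observations",
                           call. = FALSE)
  p <- ncol(y)
  gm <- colMeans(y)
  H <- matrix(0, p, p, dimnames = list(responses, responses))
  E <- matrix(0, p, p, dimnames = list(responses, responses))
  for (g in levels(grp)) {
    yg <- y[grp == g, , drop = FALSE]
    mg <- colMeans(yg)
    H <- H + nrow(yg) * tcrossprod(mg - gm)
    E <- E + crossprod(sweep(yg, 2, mg))
  }
  structure(list(H = H, E = E, df_h = length(sizes) - 1,
                 df_e = nrow(y) - length(sizes), p = p,
                 groups = levels(grp)),
            class = "sscp_pair")
}

#' The four classical multivariate test statistics
#'
#' Computes Wilks' lambda, Pillai's trace, the Hotelling-Lawley trace and
#' Roy's greatest root from an [sscp()] decomposition, together with their
#' F approximations, degrees of freedom and p-values. The eigenvalues of
#' `solve(E) %*% H` are obtained from the symmetrized generalized
#' eigenproblem via the Cholesky factor of E (never by explicit inversion).
#' Wilks uses Rao's F; Pillai and Hotelling-Lawley use the standard trace
#' approximations; Roy uses the upper-bound F, so its p-value is a lower
#' bound (significance is at most what it reports).
#'
#' @param pair An `sscp_pair` with invertible error matrix E.
#' @return A `manova_result`: list with `eigenvalues` (decreasing) and
#'   `tests`, a tibble with columns `statistic`, `value`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
manova_tests <- function(pair) {
  H <- pair$H; E <- pair$E
  p <- pair$p; df_h <- pair$df_h; df_e <- pair$df_e
  L <- tryCatch(chol(E), error = function(e) {
    stop("error SSCP matrix is singular; MANOVA statistics are undefined",
         call. = FALSE)
  })
  # M = L^-T H L^-1 shares the eigenvalues of E^-1 H and is symmetric
  Minv <- backsolve(L, t(backsolve(L, t(H), transpose = TRUE)),
                    transpose = TRUE)
  lam <- eigen((Minv + t(Minv)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(lam))) stop("non-finite eigenvalues", call. = FALSE)
  lam <- sort(pmax(lam, 0), decreasing = TRUE)
  s <- min(p, df_h)
  lam_s <- lam[seq_len(s)]
  m <- (abs(p - df_h) - 1) / 2
  n2 <- (df_e - p - 1) / 2

  wilks <- prod(1 / (1 + lam_s))
  pillai <- sum(lam_s / (1 + lam_s))
  hl <- sum(lam_s)
  roy <- lam_s[1]

  # Rao's F for Wilks
  t1 <- p * df_h
  tt <- if (p^2 + df_h^2 - 5 > 0) {
    sqrt((p^2 * df_h^2 - 4) / (p^2 + df_h^2 - 5))
  } else 1
  df2_w <- tt * (df_e + df_h - (p + df_h + 1) / 2) - (t1 - 2) / 2
  f_w <- if (wilks > 0) (1 - wilks^(1 / tt)) / wilks^(1 / tt) * df2_w / t1 else Inf

  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * n2 + s + 1)
  f_p <- if (pillai < s) ((2 * n2 + s + 1) / (2 * m + s + 1)) *
    pillai / (s - pillai) else Inf

  df1_h <- s * (2 * m + s + 1)
  df2_h <- 2 * (s * n2 + 1)
  f_h <- hl * df2_h / (s * df1_h)

  r <- max(p, df_h)
  df1_r <- r
  df2_r <- df_e - r + df_h
  f_r <- roy * df2_r / r

  tests <- tibble::tibble(
    statistic = c("Wilks", "Pillai", "Hotelling-Lawley", "Roy"),
    value = c(wilks, pillai, hl, roy),
    F = c(f_w, f_p, f_h, f_r),
    df1 = c(t1, df1_p, df1_h, df1_r),
    df2 = c(df2_w, df2_p, df2_h, df2_r)
  )
  tests$p <- stats::pf(tests$F, tests$df1, tests$df2, lower.tail = FALSE)
  structure(list(eigenvalues = lam, tests = tests),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat("<manova_result>\n")
  print(x$tests)
  invisible(x)
}

#' Run MANOVA per genus and pooled
#'
#' Runs the one-way MANOVA of the nine responses on the treatment-series
#' label (`varied_factor`) separately for every genus and once pooled over
#' all genera (genus `"all"`), and returns a tidy table of all four test
#' statistics.
#'
#' @param table An experiment table.
#' @param responses Response columns to include.
#' @param grouping Grouping column; defaults to the treatment-series label.
#' @return Tidy tibble: `genus`, `statistic`, `value`, `F`, `df1`, `df2`, `p`.
#' @export
manova_by_genus <- function(table, responses = response_names(),
                            grouping = "varied_factor") {
  genera <- sort(unique(table$genus))
  pieces <- c(split(table, table$genus)[genera], list(all = table))
  out <- purrr::imap(pieces, function(piece, g) {
    res <- manova_tests(sscp(piece, responses, grouping))
    dplyr::mutate(res$tests, genus = g, .before = 1)
  })
  dplyr::bind_rows(out)
}
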