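#' Summarize scored products by group
#'
#' Produces the surveillance-table shape: per group (any combination of
#' market, category, launch year, ...), the product count, mean and sample
#' standard deviation (n - 1 denominator; NA for single-product groups) of
#' carbohydrate, fiber and free sugars, and the percentages of products
#' meeting 10:1, 1:2, and the combined 10:1|1:2 criterion. Empty groups are
#' omitted. The combined percentage can never exceed the smaller of the two
#' component percentages (the combined verdict is a conjunction).
#'
#' @param scored scored product data frame (from [score_dataset()]).
#' @param by character vector of grouping columns, e.g.
#'   \code{c("market")} or \code{c("market", "category")}.
#' @return data frame, one row per non-empty group.
#' @export
summarize_groups <- function(scored, by = "market") {
  stopifnot(all(by %in% names(scored)))
  key <- interaction(scored[, by, drop = FALSE], drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(scored)), key), function(idx) {
    g <- scored[idx, , drop = FALSE]
    out <- g[1, by, drop = FALSE]
    out$n <- nrow(g)
    for (v in c("carbohydrate", "fiber", "free_sugars")) {
      out[[paste0(v, "_mean")]] <- mean(g[[v]])
      out[[paste0(v, "_sd")]] <- if (nrow(g) > 1L) sd(g[[v]]) else NA_real_
    }
    out$pct_meeting_10_1 <- 100 * mean(g$meets_10_1)
    out$pct_meeting_1_2 <- 100 * mean(g$meets_1_2)
    out$pct_meeting_combined <- 100 * mean(g$meets_combined)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled two-proportion z-test
#'
#' Tests equality of two binomial proportions with the pooled two-sided
#' z-test and no continuity correction:
#' \deqn{\hat p = \frac{x_a + x_b}{n_a + n_b}, \quad
#'       z = \frac{p_a - p_b}{\sqrt{\hat p (1-\hat p)(1/n_a + 1/n_b)}}}
#' with the p-value from the standard normal. Equal proportions give
#' p = 1 by definition (this also covers the zero-standard-error case).
#' A Yates continuity correction is available behind \code{correct}.
#'
#' @param count_a,n_a successes and trials in group a.
#' @param count_b,n_b successes and trials in group b.
#' @param correct apply the Yates continuity correction. Default FALSE.
#' @return object of class \code{ztest_result}: list with the counts,
#'   \code{z} and \code{p_value}. Symmetric in (a, b).
#' @examples
#' proportion_ztest(155, 485, 162, 485)  # p ~ 0.63
#' @export
proportion_ztest <- function(count_a, n_a, count_b, n_b, correct = FALSE) {
  if (n_a < 1L || n_b < 1L) stop("n must be at least 1", call. = FALSE)
  if (count_a < 0 || count_a > n_a || count_b < 0 || count_b > n_b) {
    stop("counts must lie in [0, n]", call. = FALSE)
  }
  pa <- count_a / n_a
  pb <- count_b / n_b
  if (pa == pb) {
    z <- 0
    p <- 1
  } else {
    pool <- (count_a + count_b) / (n_a + n_b)
    se <- sqrt(pool * (1 - pool) * (1 / n_a + 1 / n_b))
    diff <- pa - pb
    if (correct) {
      cc <- min(abs(diff), 0.5 * (1 / n_a + 1 / n_b))
      diff <- sign(diff) * (abs(diff) - cc)
    }
    z <- diff / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(count_a = count_a, n_a = n_a,
                 count_b = count_b, n_b = n_b,
                 z = z, p_value = p),
            class = "ztest_result")
}

#' @export
print.ztest_result <- function(x, ...) {
  cat(sprintf("two-proportion z-test: %d/%d vs %d/%d  z = %.4f  p = %.4f\n",
              x$count_a, x$n_a, x$count_b, x$n_b, x$z, x$p_value))
  invisible(x)
}

#' Recover an integer count from a printed rounded percentage
#'
#' Surveillance tables print proportions rounded to one decimal; to recompute
#' a test from such a table the underlying count must be recovered. Returns
#' the unique integer k in [0, n] with round(100 k / n) equal to the printed
#' value at the printed precision (half-away-from-zero rounding, matching
#' table style); raises an error listing the candidates when no k or several
#' k qualify.
#'
#' @param pct printed percentage.
#' @param n group size.
#' @param digits decimal places of the printed value. Default 1.
#' @return integer count.
#' @examples
#' recover_count_from_percent(32.0, 485)  # 155
#' @export
recover_count_from_percent <- function(pct, n, digits = 1L) {
  if (pct < 0 || pct > 100 || n < 1L) {
    stop("need 0 <= pct <= 100 and n >= 1", call. = FALSE)
  }
  k <- 0:n
  cand <- k[round_half_away(100 * k / n, digits) == pct]
  if (length(cand) != 1L) {
    stop("count recovery ", if (length(cand)) "ambiguous" else "impossible",
         " for ", pct, "% of ", n, " (candidates: ",
         if (length(cand)) paste(cand, collapse = ", ") else "none", ")",
         call. = FALSE)
  }
  cand
}

round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Cumulative (incremental) yearly trend of ratio adherence
#'
#' For each year Y in the window, the cumulative number of products launched
#' up to and including Y and the cumulative percentage of them meeting the
#' combined 10:1|1:2 criterion — the "incremental" series used to monitor
#' the food supply over time. At the final year the cumulative value equals
#' the whole-window proportion.
#'
#' @param scored scored product data frame with \code{launch_year}.
#' @param window length-2 integer vector (first year, last year).
#' @param by optional grouping columns (e.g. \code{"market"}); one series
#'   per group.
#' @return data frame with columns \code{by...}, \code{year},
#'   \code{cumulative_n}, \code{cumulative_pct_meeting}.
#' @export
trend_by_year <- function(scored, window = c(2014, 2024), by = NULL) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  years <- seq(window[1], window[2])
  inwin <- !is.na(scored$launch_year) &
    scored$launch_year >= window[1] & scored$launch_year <= window[2]
  scored <- scored[inwin, , drop = FALSE]
  one_series <- function(g, label) {
    do.call(rbind, lapply(years, function(y) {
      upto <- g[g$launch_year <= y, , drop = FALSE]
      row <- data.frame(year = y, cumulative_n = nrow(upto),
                        cumulative_pct_meeting = if (nrow(upto)) {
                          100 * mean(upto$meets_combined)
                        } else NA_real_)
      if (!is.null(label)) row <- cbind(label, row)
      row
    }))
  }
  if (is.null(by)) {
    out <- one_series(scored, NULL)
  } else {
    key <- interaction(scored[, by, drop = FALSE], drop = TRUE, sep = "\r")
    out <- do.call(rbind, lapply(split(seq_len(nrow(scored)), key),
      function(idx) {
        one_series(scored[idx, , drop = FALSE],
                   scored[idx[1], by, drop = FALSE])
      }))
  }
  rownames(out) <- NULL
  out
}

#' Default carbohydrate-quality positioning claims
#'
#' The marketing claims counted as signalling carbohydrate quality:
#' fiber/wholegrain claims and reduced-carb/-sugar/glycemic claims.
#'
#' @return character vector of claim names.
#' @export
carb_quality_claims <- function() {
  c("High/Added Fibre", "Wholegrain", "Low/No/Reduced Carb",
    "Low/No/Reduced Glycemic", "Low/Reduced Sugar", "No Added Sugar",
    "Diabetic")
}

#' Count products bearing carbohydrate-quality claims per market
#'
#' A product is counted once no matter how many of the listed claims it
#' bears (set semantics). Claims on the record are a pipe-separated string;
#' matching is exact after whitespace normalization, case-insensitive.
#'
#' @param products canonical product data frame with a \code{claims} column.
#' @param claim_set claims to count; default [carb_quality_claims()].
#' @return data frame per market: \code{market}, \code{n},
#'   \code{n_with_claim}, \code{pct_with_claim}.
#' @export
count_claim_products <- function(products, claim_set = carb_quality_claims()) {
  want <- norm_label(claim_set)
  has <- vapply(products$claims, function(cl) {
    if (is.na(cl) || !nzchar(cl)) return(FALSE)
    any(norm_label(strsplit(cl, "|", fixed = TRUE)[[1]]) %in% want)
  }, logical(1), USE.NAMES = FALSE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(products)),
                                     products$market), function(idx) {
    data.frame(market = products$market[idx[1]], n = length(idx),
               n_with_claim = sum(has[idx]),
               pct_with_claim = 100 * mean(has[idx]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
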