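# CMS-style small-cell suppression with secondary suppression.

#' Small-cell suppression policy
#'
#' Counts of 1-10 (inclusive) are not reported, per the Centers for
#' Medicare and Medicaid Services cell-size suppression policy; zero is
#' never suppressed. With secondary suppression on, additional cells (the
#' smallest other nonzero cell each time, first-in-column-order tie-break)
#' are masked until no suppressed cell in a margin group can be pinned
#' down by a reader who knows the row margin and that suppressed counts
#' are at least 1 -- that is, until the group has two or more masked cells
#' whose total exceeds their number. When no complementary cell is
#' eligible, the group's margin is flagged for suppression instead.
#'
#' @param suppress_range inclusive integer interval of counts to mask.
#' @param secondary_suppression protect suppressed cells from
#'   back-calculation (default TRUE).
#' @param replacement_token the mask token (default `"NR"`).
#' @return a `suppression_policy` list.
#' @export
suppression_policy <- function(suppress_range = c(1L, 10L),
                               secondary_suppression = TRUE,
                               replacement_token = "NR") {
  if (suppress_range[1] < 1 || suppress_range[2] < suppress_range[1]) {
    config_error("suppress_range",
                 "must be an ordered integer interval not containing 0")
  }
  structure(list(suppress_range = as.integer(suppress_range),
                 secondary_suppression = isTRUE(secondary_suppression),
                 replacement_token = replacement_token),
            class = "suppression_policy")
}

#' Suppress small cells in a count table
#'
#' Rows of `x` are margin groups: cells in a row are published together
#' with their row total, so a single suppressed cell in a row would be
#' recoverable by subtraction. Cells inside the policy's suppression range
#' are masked; secondary suppression then masks the smallest other nonzero
#' cell in any row with exactly one primary suppression. Applying the
#' policy to an already-masked result is a no-op (idempotence).
#'
#' @param x non-negative integer matrix or data frame of counts (rows =
#'   margin groups), or a previous `mmlot_suppressed` result.
#' @param policy a [suppression_policy()].
#' @param margins optional vector of published row margins; a mismatch
#'   with the actual row sums is a fatal validation error.
#' @return an `mmlot_suppressed` object: `masked` (character matrix with
#'   the replacement token), `values` (the original counts), `suppressed`
#'   (logical matrix), `margin_suppressed` (logical per row), `policy`.
#' @export
suppress_small_cells <- function(x, policy = suppression_policy(),
                                 margins = NULL) {
  if (inherits(x, "mmlot_suppressed")) return(x)
  m <- as.matrix(x)
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m))) {
    rlang::abort("table cells must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  if (!is.null(margins)) {
    if (length(margins) != nrow(m) || any(rowSums(m) != margins)) {
      rlang::abort("margins are inconsistent with the table rows",
                   class = "mmlot_margin_error")
    }
  }
  lo <- policy$suppress_range[1]
  hi <- policy$suppress_range[2]
  suppressed <- m >= lo & m <= hi
  margin_suppressed <- rep(FALSE, nrow(m))
  if (policy$secondary_suppression) {
    # a row is vulnerable while a reader who knows every suppressed count
    # is >= 1 can pin a cell down: one suppressed cell alone (recoverable
    # by subtraction from the margin) or suppressed cells summing to their
    # own count (all must equal 1); keep masking the smallest other
    # nonzero cell until safe, falling back to masking the row margin
    for (r in seq_len(nrow(m))) {
      repeat {
        h <- sum(suppressed[r, ])
        if (h == 0) break
        vulnerable <- h == 1 || sum(m[r, suppressed[r, ]]) == h
        if (!vulnerable) break
        cand <- which(!suppressed[r, ] & m[r, ] > 0)
        if (length(cand) > 0) {
          pick <- cand[which.min(m[r, cand])]
          suppressed[r, pick] <- TRUE
        } else {
          margin_suppressed[r] <- TRUE
          break
        }
      }
    }
  }
  masked <- matrix(as.character(m), nrow(m), ncol(m),
                   dimnames = dimnames(m))
  masked[suppressed] <- policy$replacement_token
  structure(list(masked = masked, values = m, suppressed = suppressed,
                 margin_suppressed = margin_suppressed, policy = policy),
            class = "mmlot_suppressed")
}

#' @export
print.mmlot_suppressed <- function(x, ...) {
  cat("<mmlot_suppressed> (", sum(x$suppressed), "cell(s) masked )\n")
  print(x$masked, quote = FALSE)
  invisible(x)
}

#' Format a count with percentage under suppression
#'
#' Percentages tied to a suppressed count are masked along with it.
#'
#' @param n counts; `total` denominators.
#' @param total denominators for the percentage.
#' @param suppressed logical mask (same length as `n`).
#' @param policy a [suppression_policy()] (supplies the token).
#' @return character vector of `"n (p.p)"` or the replacement token.
#' @export
format_count_pct <- function(n, total, suppressed,
                             policy = suppression_policy()) {
  ifelse(suppressed, policy$replacement_token,
         sprintf("%d (%.1f)", n, round_half_up(pct(n, total), 1)))
}
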