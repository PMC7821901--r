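# Cell-class assignment from shuffle tests, exact r x c composition tests
# (Freeman-Halton), cross-context comparison and start/stop pairing.

#' Classify a cell from its shuffle-test result
#'
#' Maps a [resampling_test()] result to one of `"excited"`, `"inhibited"`,
#' `"uncorrelated"`. When both flags are set (possible because excitation and
#' inhibition are tested separately), the direction with the more extreme
#' shuffle percentile wins and the conflict is reported as a message.
#'
#' @param result A `resampling_result`.
#' @return A single class label.
#' @export
classify_cell <- function(result) {
  stopifnot(inherits(result, "resampling_result"))
  if (result$excited && result$inhibited) {
    lab <- if (result$extremity_excited >= result$extremity_inhibited) "excited" else "inhibited"
    message(sprintf(
      "cell is both excited (percentile %.1f) and inhibited (percentile %.1f); assigned '%s'",
      100 * result$extremity_excited, 100 * result$extremity_inhibited, lab))
    return(lab)
  }
  if (result$excited) return("excited")
  if (result$inhibited) return("inhibited")
  "uncorrelated"
}

#' Freeman-Halton exact test for r x c contingency tables
#'
#' Two-sided exact test generalising Fisher's 2 x 2 test: the p-value is the
#' total multivariate-hypergeometric probability, over all tables with the
#' observed margins, of the tables whose probability does not exceed that of
#' the observed table (with a small relative tolerance for floating-point
#' ties). Tables are enumerated exhaustively; the grand total is capped by
#' `enum_limit`.
#'
#' @param x Matrix or table of nonnegative integer counts. All-zero rows and
#'   columns are dropped with a warning.
#' @param enum_limit Maximum grand total for exhaustive enumeration
#'   (default 200).
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, 2))  # 34/70
fisher_exact_rxc <- function(x, enum_limit = 200) {
  x <- as.matrix(unclass(x))
  if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-9)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  x <- round(x)
  zr <- rowSums(x) == 0; zc <- colSums(x) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero rows/columns", call. = FALSE)
    x <- x[!zr, !zc, drop = FALSE]
  }
  N <- sum(x)
  if (N == 0) stop("table total must be positive", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2) return(1)
  if (N > enum_limit) {
    stop("table total ", N, " exceeds enum_limit (", enum_limit,
         "); raise enum_limit to enumerate", call. = FALSE)
  }
  rs <- rowSums(x); cs <- colSums(x)
  lfact <- lgamma(seq_len(N + 1))        # lfact[k + 1] = log(k!)
  lf <- function(k) lfact[k + 1L]
  const <- sum(lf(rs)) + sum(lf(cs)) - lf(N)
  logp_obs <- const - sum(lf(as.vector(x)))
  tol <- 1e-9   # log-space tie tolerance, far below any genuine gap at n <= 200

  r <- nrow(x); cc <- ncol(x)
  total_p <- 0
  # DFS over rows; within a row over cells, with the last cell and last row
  # forced by the margins
  rec_row <- function(i, colrem, acc) {
    if (i == r) {
      if (any(colrem < 0)) return(invisible())
      logp <- const - (acc + sum(lf(colrem)))
      if (logp <= logp_obs + tol) total_p <<- total_p + exp(logp)
      return(invisible())
    }
    rec_cell <- function(j, left, colrem, acc) {
      if (j == cc) {
        if (left > colrem[cc]) return(invisible())
        colrem[cc] <- colrem[cc] - left
        rec_row(i + 1L, colrem, acc + lf(left))
        return(invisible())
      }
      for (v in 0:min(left, colrem[j])) {
        colrem2 <- colrem; colrem2[j] <- colrem2[j] - v
        rec_cell(j + 1L, left - v, colrem2, acc + lf(v))
      }
    }
    rec_cell(1L, rs[i], colrem, acc)
  }
  rec_row(1L, cs, 0)
  min(1, total_p)
}

#' Cell-class composition test between groups
#'
#' Builds the group x class contingency table (e.g. medial vs lateral implant
#' location against excited / inhibited / uncorrelated) and tests whether the
#' composition differs between groups with the exact [fisher_exact_rxc()]
#' test.
#'
#' @param cells Tibble with one row per cell.
#' @param group_by Name of the grouping column (default `"location"`).
#' @param class_of Name of the class column (default `"class"`).
#' @param enum_limit Passed to [fisher_exact_rxc()].
#' @return A `composition_test` list: `table` (counts), `p_value`.
#' @export
composition_test <- function(cells, group_by = "location", class_of = "class",
                             enum_limit = 200) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0) stop("empty cell set", call. = FALSE)
  if (!all(c(group_by, class_of) %in% names(cells))) {
    stop("cells must have columns '", group_by, "' and '", class_of, "'", call. = FALSE)
  }
  g <- as.character(cells[[group_by]])
  cl <- factor(as.character(cells[[class_of]]),
               levels = union(c("excited", "inhibited", "uncorrelated"),
                              unique(cells[[class_of]])))
  if (length(unique(g)) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(as.character(cl))) < 2) stop("need at least 2 classes present", call. = FALSE)
  tab <- table(group = g, class = droplevels(cl))
  structure(list(table = tab, p_value = fisher_exact_rxc(tab, enum_limit)),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  print(x$table)
  cat(sprintf("Freeman-Halton exact test: P = %.4g\n", x$p_value))
  invisible(x)
}

# Shared pairing logic for cross-context and start/stop comparisons.
pair_results <- function(results_a, results_b, suffixes, label_a, label_b) {
  need <- c("cell_id", "class", "peak")
  stopifnot(all(need %in% names(results_a)), all(need %in% names(results_b)))
  paired <- inner_join(
    results_a %>% select(all_of(need)),
    results_b %>% select(all_of(need)),
    by = "cell_id", suffix = suffixes
  )
  if (nrow(paired) == 0) stop("no shared cell ids", call. = FALSE)
  ca <- paired[[paste0("class", suffixes[1])]]
  cb <- paired[[paste0("class", suffixes[2])]]
  sig_a <- ca != "uncorrelated"; sig_b <- cb != "uncorrelated"
  paired <- paired[sig_a | sig_b, , drop = FALSE]
  ca <- ca[sig_a | sig_b]; cb <- cb[sig_a | sig_b]
  both <- ca != "uncorrelated" & cb != "uncorrelated"
  counts <- tibble(
    n_shared = nrow(paired),
    n_both_significant = sum(both),
    n_same_sign = sum(both & ca == cb),
    n_opposite_sign = sum(both & ca != cb),
    n_only_first = sum(ca != "uncorrelated" & cb == "uncorrelated"),
    n_only_second = sum(cb != "uncorrelated" & ca == "uncorrelated"),
    n_excited_both = sum(ca == "excited" & cb == "excited"),
    n_inhibited_both = sum(ca == "inhibited" & cb == "inhibited")
  )
  structure(list(paired = as_tibble(paired), counts = counts,
                 labels = c(label_a, label_b)),
            class = "paired_comparison")
}

#' Compare per-cell results across two behavioural contexts
#'
#' Restricts shared cells to those significantly modulated in at least one
#' context, pairs their response peaks (e.g. treadmill vs open field) and
#' counts class consistency across contexts.
#'
#' @param results_a,results_b Tibbles with columns `cell_id`, `class`, `peak`.
#' @return A `paired_comparison` list: `paired` (tibble with `peak_a`,
#'   `peak_b`, `class_a`, `class_b`) and `counts`.
#' @export
cross_context_compare <- function(results_a, results_b) {
  pair_results(results_a, results_b, c("_a", "_b"), "context_a", "context_b")
}

#' Pair start- and stop-related results per cell
#'
#' Same pairing as [cross_context_compare()] but across behaviours: cells
#' significant for stops and/or starts, with counts of same- and
#' opposite-sign modulation among cells significant for both.
#'
#' @param stop_results,start_results Tibbles with columns `cell_id`, `class`,
#'   `peak`.
#' @return A `paired_comparison` list (suffixes `_stop`, `_start`).
#' @export
start_stop_pairing <- function(stop_results, start_results) {
  pair_results(stop_results, start_results, c("_stop", "_start"), "stop", "start")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired comparison (", x$labels[1], " vs ", x$labels[2], ")\n", sep = "")
  print(x$counts)
  invisible(x)
}
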