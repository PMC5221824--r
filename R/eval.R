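#' Pathway sequences for evaluation
#'
#' A light container pairing the ordered compound chain of a pathway with its
#' ordered reaction chain, as used when comparing a computed pathway with a
#' reference (known) pathway.
#'
#' @param compounds Ordered character vector of compound ids.
#' @param reactions Ordered character vector of reaction ids; when both
#'   chains are given their lengths must be consistent
#'   (`length(reactions) == length(compounds) - 1`).
#' @return An object of class `pathway_sequence`.
#' @export
pathway_sequence <- function(compounds = character(), reactions = character()) {
  compounds <- as.character(compounds)
  reactions <- as.character(reactions)
  if (length(compounds) && length(reactions) &&
      length(reactions) != length(compounds) - 1L) {
    abort_domain("expected one reaction per step: length(reactions) == length(compounds) - 1.")
  }
  structure(list(compounds = compounds, reactions = reactions),
            class = "pathway_sequence")
}

#' @export
print.pathway_sequence <- function(x, ...) {
  cat(sprintf("<pathway_sequence> %s\n", paste(x$compounds, collapse = " -> ")))
  invisible(x)
}

as_pathway_sequence <- function(x) {
  if (inherits(x, "pathway_sequence")) return(x)
  if (is.character(x)) return(pathway_sequence(compounds = x))
  if (is.list(x) && !is.null(x$compounds)) {
    return(pathway_sequence(x$compounds, x$reactions %||% character()))
  }
  abort_domain("cannot interpret input as a pathway sequence.")
}

# Sequences of a pathway_set, one pathway_sequence per rank.
pathway_set_sequences <- function(ps) {
  lapply(seq_len(nrow(ps)), function(i) {
    pathway_sequence(ps$compounds[[i]], ps$reactions[[i]])
  })
}

# Longest common subsequence of two duplicate-free sequences, returning the
# matched items. Among equal-length solutions the one matching the earliest
# positions of the known sequence is chosen (when skipping is free, the
# computed index advances first).
lcs_items <- function(computed, known) {
  n <- length(computed)
  m <- length(known)
  # L[i, j] = LCS length of computed[i..n] and known[j..m] (suffixes)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in n:1) {
    for (j in m:1) {
      L[i, j] <- if (computed[i] == known[j]) {
        1L + L[i + 1L, j + 1L]
      } else {
        max(L[i + 1L, j], L[i, j + 1L])
      }
    }
  }
  out <- character()
  i <- 1L; j <- 1L
  while (i <= n && j <= m && L[i, j] > 0L) {
    if (computed[i] == known[j] && L[i, j] == 1L + L[i + 1L, j + 1L]) {
      out <- c(out, computed[i])
      i <- i + 1L; j <- j + 1L
    } else if (L[i + 1L, j] == L[i, j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  out
}

#' Order-respecting shared items of two pathways
#'
#' The correct items of a computed pathway are the items that occur in both
#' the computed and the known pathway *in the same relative order*. The
#' maximal such set is a longest common subsequence of the two chains; ties
#' between equal-length solutions are broken by preferring matches that occur
#' earlier in the known chain. Duplicate ids within a chain are collapsed to
#' their first occurrence before matching.
#'
#' @param computed,known Ordered character vectors of ids (compounds or
#'   reactions).
#' @return Character vector of the correct items, in pathway order.
#' @examples
#' correct_items(c("A", "C", "B", "D"), c("A", "B", "C", "D"))  # A B D
#' @export
correct_items <- function(computed, known) {
  computed <- unique(as.character(computed))
  known <- unique(as.character(known))
  if (!length(computed) || !length(known)) {
    abort_domain("both sequences must be nonempty.")
  }
  lcs_items(computed, known)
}

#' Score a computed pathway against a known pathway
#'
#' Order-respecting inclusion metrics at the compound or the reaction level.
#' True positives are the [correct_items()]; false negatives the known items
#' not matched; false positives the computed items not matched. From these:
#' sensitivity `sn = tp / (tp + fn)`, positive predictive value
#' `ppv = tp / (tp + fp)`, accuracy `ac = (sn + ppv) / 2` (no true negatives
#' exist in this comparison) and F-measure `fm = 2 * ppv * sn / (ppv + sn)`.
#'
#' The error rate reported here, `er = (fp + fn) / (tp + fp + fn)`, is a
#' symmetric mismatch surrogate in \[0, 1\] that is 0 exactly when the two
#' chains coincide; it is this package's own definition, not a
#' cross-validation estimate.
#'
#' @param computed,known A [pathway_sequence()], a plain character vector of
#'   ids, or a list with `compounds`/`reactions`.
#' @param level `"compounds"` (default) or `"reactions"`.
#' @return A one-row tibble: `level`, `tp`, `fn`, `fp`, `sn`, `ppv`, `ac`,
#'   `fm`, `er`.
#' @examples
#' score_pathway(c("A", "X", "C"), c("A", "B", "C"))
#' @export
score_pathway <- function(computed, known, level = c("compounds", "reactions")) {
  level <- match.arg(level)
  comp <- eval_chain(computed, level)
  ref <- eval_chain(known, level)
  if (!length(comp) || !length(ref)) {
    abort_domain(sprintf("the %s chain of both pathways must be nonempty.", level))
  }
  comp <- unique(comp)
  ref <- unique(ref)
  hits <- lcs_items(comp, ref)
  tp <- length(hits)
  fn <- length(ref) - tp
  fp <- length(comp) - tp
  ratio <- function(num, den, what) {
    if (den == 0L) {
      warn(sprintf("%s undefined (denominator 0); reported as 0.", what))
      return(0)
    }
    num / den
  }
  sn <- ratio(tp, tp + fn, "sensitivity")
  ppv <- ratio(tp, tp + fp, "positive predictive value")
  ac <- (sn + ppv) / 2
  fm <- if (ppv + sn == 0) 0 else 2 * ppv * sn / (ppv + sn)
  er <- ratio(fp + fn, tp + fp + fn, "error rate")
  tibble(level = level, tp = tp, fn = fn, fp = fp,
         sn = sn, ppv = ppv, ac = ac, fm = fm, er = er)
}

eval_chain <- function(x, level) {
  if (is.character(x)) return(x)
  s <- as_pathway_sequence(x)
  if (level == "compounds") s$compounds else s$reactions
}

#' Best-scoring pathway among the top k
#'
#' Scores every candidate against the known pathway and returns the metrics
#' of the best one: highest accuracy, ties broken by higher F-measure, then
#' by lower rank (earlier in the list).
#'
#' @param candidates A `pathway_set`, or a list of sequences accepted by
#'   [score_pathway()].
#' @param known The known pathway.
#' @param level `"compounds"` or `"reactions"`.
#' @return A one-row tibble as in [score_pathway()], plus a `rank` column
#'   giving the 1-based position of the winning candidate.
#' @export
best_of_top_k <- function(candidates, known, level = c("compounds", "reactions")) {
  level <- match.arg(level)
  if (inherits(candidates, "pathway_set")) {
    candidates <- pathway_set_sequences(candidates)
  }
  if (!length(candidates)) abort_domain("`candidates` must be nonempty.")
  scores <- dplyr::bind_rows(lapply(candidates, score_pathway, known = known,
                                    level = level))
  scores$rank <- seq_len(nrow(scores))
  best <- scores[order(-scores$ac, -scores$fm, scores$rank), ][1, ]
  best[, c("rank", setdiff(names(best), "rank"))]
}

#' Read reference pathways from a TSV file
#'
#' Expected columns: `pathway_id`, `compound_chain` (comma-separated ids),
#' `reaction_chain` (comma-separated ids, may be empty).
#'
#' @param path File path.
#' @return A tibble with `pathway_id` and list-columns `compounds`,
#'   `reactions`.
#' @export
read_reference_pathways <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file '%s' does not exist.", path))
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("pathway_id", "compound_chain") %in% names(d))) {
    abort_parse(sprintf("'%s': expected columns pathway_id, compound_chain.", path))
  }
  if (!"reaction_chain" %in% names(d)) d$reaction_chain <- NA_character_
  split_chain <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  tibble(
    pathway_id = d$pathway_id,
    compounds = lapply(d$compound_chain, split_chain),
    reactions = lapply(d$reaction_chain, split_chain)
  )
}
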