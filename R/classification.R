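#' Parse a CATH hierarchy code
#'
#' A code names a node of the CATH hierarchy: Class.Architecture.Topology
#' for a topology (fold, T) level node, with a fourth Homologous
#' superfamily field for an H-level node ("3.40.50.300").
#'
#' @param text code string, "C.A.T" or "C.A.T.H".
#' @return object of class `cath_code` with integer fields `c`, `a`, `t`
#'   and optionally `h`, and a `level` of "T" or "H".
#' @export
cath_code <- function(text) {
  if (inherits(text, "cath_code")) return(text)
  parts <- strsplit(trimws(text), ".", fixed = TRUE)[[1]]
  if (!length(parts) %in% c(3L, 4L) || anyNA(suppressWarnings(as.integer(parts))))
    stop("malformed CATH code: '", text, "'")
  parts <- as.integer(parts)
  structure(list(c = parts[1], a = parts[2], t = parts[3],
                 h = if (length(parts) == 4L) parts[4] else NULL),
            class = "cath_code")
}

#' @export
format.cath_code <- function(x, ...) {
  paste(c(x$c, x$a, x$t, x$h), collapse = ".")
}

#' @export
as.character.cath_code <- function(x, ...) format(x)

#' @export
print.cath_code <- function(x, ...) {
  cat(sprintf("<cath_code %s (%s level)>\n", format(x), cath_level(x)))
  invisible(x)
}

#' Depth of a CATH code
#'
#' @param code a `cath_code` (or string).
#' @return "H" if the superfamily field is present, else "T".
#' @export
cath_level <- function(code) {
  code <- cath_code(code)
  if (is.null(code$h)) "T" else "H"
}

#' Truncate a CATH code to topology level
#'
#' @param code a `cath_code` (or string).
#' @return the C.A.T prefix as a `cath_code`.
#' @export
cath_topology <- function(code) {
  code <- cath_code(code)
  code$h <- NULL
  code
}

#' Assign a CATH label to a domain from structure-search hits
#'
#' Implements the label routing used when search results from a
#' structure-similarity tool and a nearest-neighbour embedding search are
#' combined: the best structure-search hit with a full superfamily code
#' at or above `score_min` yields an H-level label; failing that, the
#' best topology-only structure hit or any nearest-neighbour hit yields a
#' T-level label (nearest-neighbour matches are always counted at
#' topology level); otherwise the domain is unlabelled. Ties are broken
#' by higher score, then lexicographically smaller target code.
#'
#' @param hits data.frame with columns `query`, `target_code`, `score`
#'   (normalised to `[0, 1]`), `kind` ("structure_search" or
#'   "nearest_neighbour"); may have zero rows.
#' @param score_min minimum score for a structure-search hit to count
#'   (default 0.5). Nearest-neighbour hits are not thresholded.
#' @return object of class `domain_label`: `domain_id`, `level` ("H",
#'   "T" or "none"), `code` (a `cath_code` or NULL) and `source`.
#' @export
assign_label <- function(hits, score_min = 0.5) {
  domain_id <- if (nrow(hits) > 0L) as.character(hits$query[1]) else NA_character_
  none <- structure(list(domain_id = domain_id, level = "none",
                         code = NULL, source = NA_character_),
                    class = "domain_label")
  if (nrow(hits) == 0L) return(none)
  if (!all(hits$kind %in% c("structure_search", "nearest_neighbour")))
    stop("unknown hit kind: ",
         paste(setdiff(hits$kind, c("structure_search", "nearest_neighbour")),
               collapse = ", "))
  invisible(lapply(hits$target_code, cath_code))  # validates every code
  hits <- hits[order(-hits$score, as.character(hits$target_code)), , drop = FALSE]

  h_cand <- hits$kind == "structure_search" & hits$score >= score_min &
    vapply(hits$target_code, function(x) cath_level(x) == "H", logical(1))
  if (any(h_cand)) {
    top <- which(h_cand)[1]
    return(structure(list(domain_id = domain_id, level = "H",
                          code = cath_code(hits$target_code[top]),
                          source = "structure_search"),
                     class = "domain_label"))
  }
  t_cand <- (hits$kind == "structure_search" & hits$score >= score_min) |
    hits$kind == "nearest_neighbour"
  if (any(t_cand)) {
    top <- which(t_cand)[1]
    return(structure(list(domain_id = domain_id, level = "T",
                          code = cath_topology(hits$target_code[top]),
                          source = hits$kind[top]),
                     class = "domain_label"))
  }
  none
}

#' @export
print.domain_label <- function(x, ...) {
  cat(sprintf("<domain_label %s: %s%s>\n", x$domain_id, x$level,
              if (x$level == "none") "" else
                sprintf(" %s (%s)", format(x$code), x$source)))
  invisible(x)
}

#' Partition sequence clusters by label status
#'
#' A cluster is labelled if at least one member domain carries a CATH
#' label at any level; the label is not pushed onto unlabelled members,
#' only the cluster-level status is recorded (coverage is counted at
#' cluster level).
#'
#' @param clusters data.frame with columns `cluster_id`, `domain_id`
#'   (long form, one row per member).
#' @param labels named character vector (or data.frame `domain_id`,
#'   `level`) giving each member's label level ("H", "T" or "none").
#'   Every member must be present.
#' @return list with `labelled_clusters` and `unlabelled_clusters`
#'   (character vectors of cluster ids) and `member_counts` (named).
#' @export
propagate_cluster_labels <- function(clusters, labels) {
  if (is.data.frame(labels))
    labels <- setNames(as.character(labels$level), labels$domain_id)
  unknown <- setdiff(clusters$domain_id, names(labels))
  if (length(unknown) > 0L)
    stop("no label record for member(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  lev <- labels[clusters$domain_id]
  has_label <- tapply(lev != "none", clusters$cluster_id, any)
  ids <- names(has_label)
  counts <- tapply(clusters$domain_id, clusters$cluster_id, length)
  list(labelled_clusters = ids[has_label],
       unlabelled_clusters = ids[!has_label],
       member_counts = setNames(as.integer(counts), names(counts)))
}

#' Cross-validate a structure-derived label against an HMM scan
#'
#' Compares the CATH code assigned by structure search with the code of
#' the best sequence-HMM hit for the same domain: exact superfamily
#' (C.A.T.H) agreement confirms the superfamily; agreement of the C.A.T
#' prefix with a differing or absent H field confirms the fold only;
#' disagreement within C.A.T leaves the label unconfirmed.
#'
#' @param struct_label a `domain_label` (level "H" or "T") or a code.
#' @param hmm_code the HMM hit's `cath_code` (or string), or NULL when
#'   the scan produced no hit.
#' @return one of "confirmed_superfamily", "confirmed_fold",
#'   "unconfirmed", "no_hmm_hit".
#' @export
validate_with_hmm <- function(struct_label, hmm_code = NULL) {
  code <- if (inherits(struct_label, "domain_label")) {
    if (struct_label$level == "none")
      stop("cannot validate an unlabelled domain")
    struct_label$code
  } else cath_code(struct_label)
  if (is.null(hmm_code) || (length(hmm_code) == 1L && is.na(hmm_code)))
    return("no_hmm_hit")
  hmm_code <- cath_code(hmm_code)
  same_cat <- identical(format(cath_topology(code)), format(cath_topology(hmm_code)))
  if (!same_cat) return("unconfirmed")
  if (!is.null(code$h) && !is.null(hmm_code$h) && code$h == hmm_code$h)
    return("confirmed_superfamily")
  "confirmed_fold"
}

#' Bin a plDDT value into AFDB confidence classes
#'
#' Bins follow the AFDB convention with closed lower bounds: very high
#' (plDDT >= 90), high (90 > plDDT >= 70), low (70 > plDDT >= 50) and
#' very low (plDDT < 50).
#'
#' @param value numeric vector of plDDT values in `[0, 100]`.
#' @return character vector of "very_high", "high", "low", "very_low".
#' @export
plddt_bin <- function(value) {
  if (any(!is.finite(value)) || any(value < 0 | value > 100))
    stop("plDDT values must lie in [0, 100]")
  out <- character(length(value))
  out[value >= 90] <- "very_high"
  out[value < 90 & value >= 70] <- "high"
  out[value < 70 & value >= 50] <- "low"
  out[value < 50] <- "very_low"
  out
}
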