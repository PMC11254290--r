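#' Build a cause--effect gene-set pair collection
#'
#' One pair per patient/condition: a cause set (e.g. mutated or copy-number
#' altered genes, assumed upstream) and an effect set (e.g. differentially
#' expressed genes, assumed downstream).
#'
#' @param causes,effects lists of character vectors, equal length.
#' @param ids optional labels (e.g. patient ids); defaults to
#'   \code{pair1, pair2, ...}.
#' @return object of class \code{ce_pairs}: a list of pairs, each with
#'   \code{id}, \code{causes}, \code{effects}.
#' @export
ce_pairs <- function(causes, effects, ids = NULL) {
  stopifnot(length(causes) == length(effects))
  if (is.null(ids)) ids <- paste0("pair", seq_along(causes))
  out <- Map(function(id, cs, es) {
    cs <- unique(as.character(cs)); es <- unique(as.character(es))
    if (!length(cs)) stop(sprintf("pair '%s' has an empty cause set", id))
    if (!length(es)) stop(sprintf("pair '%s' has an empty effect set", id))
    list(id = id, causes = cs, effects = es)
  }, as.character(ids), causes, effects)
  names(out) <- NULL
  structure(out, class = "ce_pairs")
}

#' @export
print.ce_pairs <- function(x, ...) {
  cat(sprintf("ce_pairs: %d cause-effect pairs (mean |C| = %.1f, mean |E| = %.1f)\n",
              length(x),
              mean(vapply(x, function(p) length(p$causes), 1)),
              mean(vapply(x, function(p) length(p$effects), 1))))
  invisible(x)
}

#' @export
`[.ce_pairs` <- function(x, i) structure(unclass(x)[i], class = "ce_pairs")

#' Read cause--effect pairs from a two-row gene-set file
#'
#' GMT-like dialect: two consecutive tab-separated records per pair,
#' \code{<id> TAB CAUSE TAB gene...} followed by
#' \code{<id> TAB EFFECT TAB gene...}.
#'
#' @param path file path.
#' @return a [ce_pairs()] collection in file order.
#' @export
load_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 2L != 0L)
    stop("odd number of records: every pair needs a CAUSE and an EFFECT row")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("malformed line %d: expected <id> TAB CAUSE|EFFECT TAB genes...", bad[1]))
  ids <- vapply(parts, `[[`, "", 1L)
  tags <- vapply(parts, `[[`, "", 2L)
  if (!all(tags %in% c("CAUSE", "EFFECT")))
    stop(sprintf("unknown record tag '%s'", setdiff(tags, c("CAUSE", "EFFECT"))[1]))
  odd <- seq(1L, length(lines), by = 2L)
  if (any(tags[odd] != "CAUSE") || any(tags[odd + 1L] != "EFFECT") ||
      any(ids[odd] != ids[odd + 1L])) {
    k <- which(tags[odd] != "CAUSE" | tags[odd + 1L] != "EFFECT" |
                 ids[odd] != ids[odd + 1L])[1]
    stop(sprintf("unpaired record for id '%s' (line %d)", ids[odd[k]], odd[k]))
  }
  genes <- lapply(parts, function(p) p[-(1:2)])
  ce_pairs(causes = genes[odd], effects = genes[odd + 1L], ids = ids[odd])
}

#' Write cause--effect pairs in the two-row gene-set dialect
#' @param pairs a [ce_pairs()] collection.
#' @param path output file.
#' @export
write_pairs <- function(pairs, path) {
  lines <- unlist(lapply(pairs, function(p) {
    c(paste(c(p$id, "CAUSE", p$causes), collapse = "\t"),
      paste(c(p$id, "EFFECT", p$effects), collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Drop pairs with oversized gene sets
#'
#' A pair survives only if both its cause set and its effect set have at
#' most \code{max_set_size} genes (default 1000, a strict \code{> 1000}
#' removal rule). Oversized guiding sets carry little directional signal
#' and dominate propagation mass.
#'
#' @param pairs a [ce_pairs()] collection.
#' @param max_set_size maximum allowed set size.
#' @return the filtered collection, order preserved.
#' @export
filter_pairs <- function(pairs, max_set_size = 1000L) {
  keep <- vapply(pairs, function(p) {
    length(p$causes) <= max_set_size && length(p$effects) <= max_set_size
  }, TRUE)
  if (!all(keep))
    message(sprintf("filter_pairs: removed %d of %d pairs with a set > %d genes",
                    sum(!keep), length(pairs), max_set_size))
  structure(unclass(pairs)[keep], class = "ce_pairs")
}
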