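#' Allowed activator/repressor role (ARR) values
#'
#' A pathway member's role is a discrete signed coefficient: +1 full
#' activator, -1 full repressor, +/-0.5 intermediate, 0 neutral/undefined.
#' @export
ARR_LEVELS <- c(-1, -0.5, 0, 0.5, 1)

#' Construct a pathway catalog
#'
#' A pathway catalog is a data frame with columns `pathway`, `gene` and
#' `arr` (class `pas_catalog`), one row per pathway member. The `arr`
#' column holds the signed activator/repressor role of the gene product
#' *within that pathway*; the same gene may appear in several pathways
#' with different roles.
#'
#' @param df data frame with character columns `pathway`, `gene` and a
#'   numeric column `arr`.
#' @return validated `pas_catalog` data frame, row order preserved.
#' @details Validation enforces: non-empty catalog; `arr` values exactly in
#'   `ARR_LEVELS`; unique `(pathway, gene)` pairs; every pathway has at
#'   least one member with a nonzero role (a pathway of only neutral
#'   members cannot be scored). Gene identifiers are opaque,
#'   case-sensitive strings; no symbol aliasing is attempted.
#' @export
#' @examples
#' pas_catalog(data.frame(pathway = "P1", gene = c("G1", "G2"),
#'                        arr = c(1, -1)))
pas_catalog <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("pathway", "gene", "arr")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[, need, drop = FALSE]
  df$pathway <- as.character(df$pathway)
  df$gene <- as.character(df$gene)
  df$arr <- as.numeric(df$arr)
  if (nrow(df) == 0L) stop("empty catalog: no pathway members")
  if (any(is.na(df$pathway)) || any(!nzchar(df$pathway))) {
    stop("pathway names must be non-empty strings")
  }
  if (any(is.na(df$gene)) || any(!nzchar(df$gene))) {
    stop("gene symbols must be non-empty strings")
  }
  bad <- which(!(df$arr %in% ARR_LEVELS))
  if (length(bad) > 0L) {
    stop("arr value ", df$arr[bad[1L]], " for gene '", df$gene[bad[1L]],
         "' in pathway '", df$pathway[bad[1L]],
         "' is not one of {-1, -0.5, 0, 0.5, 1}")
  }
  key <- paste(df$pathway, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop("duplicate gene '", parts[2L], "' in pathway '", parts[1L], "'")
  }
  allzero <- tapply(df$arr, df$pathway, function(a) all(a == 0))
  if (any(allzero)) {
    stop("pathway '", names(allzero)[which(allzero)[1L]],
         "' has no member with a nonzero activator/repressor role")
  }
  rownames(df) <- NULL
  class(df) <- c("pas_catalog", "data.frame")
  df
}

#' Read a pathway catalog from a TSV file
#'
#' Expects a UTF-8 tab-separated file with header
#' `pathway<TAB>gene<TAB>arr` and one pathway member per line. Lines
#' starting with `#` are skipped. Row order in the file is preserved in
#' the catalog (pathways are scored in file order).
#'
#' @param path path to the catalog file.
#' @return a [pas_catalog()] data frame.
#' @export
load_pathway_catalog <- function(path) {
  if (!file.exists(path)) stop("pathway catalog file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "#", colClasses = "character",
                      check.names = FALSE),
    error = function(e) stop("cannot parse pathway catalog '", path, "': ",
                             conditionMessage(e)))
  need <- c("pathway", "gene", "arr")
  if (!all(need %in% names(df))) {
    stop("pathway catalog '", path, "' must have header columns ",
         "pathway, gene, arr")
  }
  if (nrow(df) == 0L) stop("empty catalog (header only): ", path)
  arr <- suppressWarnings(as.numeric(df$arr))
  bad <- which(is.na(arr))
  if (length(bad) > 0L) {
    stop("malformed arr value '", df$arr[bad[1L]], "' at data line ",
         bad[1L], " of ", path)
  }
  df$arr <- arr
  pas_catalog(df)
}

#' Write a pathway catalog to a TSV file
#'
#' Inverse of [load_pathway_catalog()]; `arr` is printed so the five
#' allowed role values round-trip exactly (-1, -0.5, 0, 0.5, 1).
#'
#' @param catalog a `pas_catalog`.
#' @param path output file path.
#' @param header_lines optional character vector of `#`-prefixed comment
#'   lines written before the column header.
#' @return `path`, invisibly.
#' @export
write_pathway_catalog <- function(catalog, path, header_lines = character()) {
  stopifnot(inherits(catalog, "pas_catalog"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0L) writeLines(header_lines, con)
  writeLines("pathway\tgene\tarr", con)
  writeLines(paste(catalog$pathway, catalog$gene,
                   format(catalog$arr, trim = TRUE, scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' Summarize a pathway catalog
#'
#' @param catalog a `pas_catalog`.
#' @return data frame with one row per pathway (catalog order):
#'   `pathway`, `n_genes`, `n_activators` (arr > 0), `n_repressors`
#'   (arr < 0), `n_neutral` (arr = 0).
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "pas_catalog"))
  pws <- unique(catalog$pathway)
  out <- do.call(rbind, lapply(pws, function(p) {
    a <- catalog$arr[catalog$pathway == p]
    data.frame(pathway = p, n_genes = length(a),
               n_activators = sum(a > 0), n_repressors = sum(a < 0),
               n_neutral = sum(a == 0), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Extract one pathway's member table
#'
#' @param catalog a `pas_catalog`.
#' @param name pathway identifier.
#' @return data frame with columns `gene`, `arr` in catalog order.
#' @export
catalog_pathway <- function(catalog, name) {
  stopifnot(inherits(catalog, "pas_catalog"))
  rows <- catalog[catalog$pathway == name, c("gene", "arr")]
  if (nrow(rows) == 0L) stop("pathway not in catalog: ", name)
  rownames(rows) <- NULL
  class(rows) <- "data.frame"
  rows
}
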