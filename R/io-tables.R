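# Readers and writers for all tabular inputs and outputs. All on-disk formats
# are TSV with a mandatory header; lines starting with "#" are comments.
# Writers are deterministic: canonical row order and doubles at 6 significant
# digits, so identical objects always produce byte-identical files.

readTsvLines <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a protein-protein interaction edge list
#'
#' Each non-comment line must hold at least two tab-separated gene
#' identifiers; extra columns (e.g. interaction evidence) are ignored.
#' Duplicate and reversed pairs as well as self-loops are returned as-is;
#' collapsing to a simple graph is deferred to [buildNetwork()].
#'
#' @param path path to a TSV edge list. A header line is permitted only as a
#'   `#`-prefixed comment.
#' @return data.frame with character columns `p1`, `p2`, one row per pair.
#' @examples
#' f <- tempfile(); writeLines(c("#p1\tp2", "A\tB", "B\tA"), f)
#' readEdgeList(f)
#' @export
readEdgeList <- function(path) {
  tl <- readTsvLines(path)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("malformed edge line %d in '%s': fewer than 2 fields",
                 tl$lineno[bad[1L]], path))
  data.frame(p1 = asGeneIds(vapply(parts, `[[`, character(1), 1L)),
             p2 = asGeneIds(vapply(parts, `[[`, character(1), 2L)))
}

tableSchemas <- list(
  expression = list(cols = c("gene", "fpkm"),       numeric = "fpkm"),
  dea        = list(cols = c("gene", "log2fc", "padj"),
                    numeric = c("log2fc", "padj")),
  splicing   = list(cols = c("gene", "fdr"),        numeric = "fdr"),
  disease    = list(cols = c("gene", "linked"),     numeric = "linked"),
  annotation = list(cols = c("term_id", "term_name", "gene"),
                    numeric = character(0)))

#' Read a typed analysis table
#'
#' Parses one of the five tabular inputs. Required columns per schema:
#' `expression` (gene, fpkm), `dea` (gene, log2fc, padj), `splicing`
#' (gene, fdr), `disease` (gene, linked), `annotation` (term_id, term_name,
#' gene). Extra columns are ignored. Values of `padj`/`fdr` that fail numeric
#' parsing become `NA` and are treated downstream as non-significant;
#' out-of-range probabilities, negative FPKM, non-binary disease flags and
#' duplicated gene rows are errors. Output rows are canonically sorted, so
#' loading is insensitive to the row order of the input file.
#'
#' @param path path to a TSV file with a header row.
#' @param schema one of `"expression"`, `"dea"`, `"splicing"`, `"disease"`,
#'   `"annotation"`.
#' @return data.frame in the schema's column order. `linked` is returned as
#'   logical; annotation rows are unique on (term_id, gene).
#' @export
readTable <- function(path, schema = names(tableSchemas)) {
  schema <- match.arg(schema)
  sc <- tableSchemas[[schema]]
  tl <- readTsvLines(path)
  if (!length(tl$lines))
    stop("no header found in '", path, "'")
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  missingCols <- setdiff(sc$cols, header)
  if (length(missingCols))
    stop(sprintf("schema '%s': missing required column '%s' in '%s'",
                 schema, missingCols[1L], path))
  rows <- parts[-1L]
  short <- which(lengths(rows) < length(header))
  if (length(short))
    stop(sprintf("malformed line %d in '%s': fewer fields than header",
                 tl$lineno[-1L][short[1L]], path))
  df <- as.data.frame(
    stats::setNames(lapply(match(sc$cols, header),
                           function(j) vapply(rows, `[[`, character(1), j)),
                    sc$cols))
  if (nrow(df) == 0L)
    df <- stats::setNames(
      as.data.frame(lapply(sc$cols, function(x) character(0))), sc$cols)
  for (cl in sc$numeric)
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))

  if (schema == "annotation") {
    df$gene <- asGeneIds(df$gene)
    df <- unique(df)
    df <- df[order(df$term_id, df$gene), , drop = FALSE]
  } else {
    df$gene <- asGeneIds(df$gene)
    if (anyDuplicated(df$gene))
      stop(sprintf("schema '%s': duplicate gene row '%s' in '%s'",
                   schema, df$gene[duplicated(df$gene)][1L], path))
    df <- df[order(df$gene), , drop = FALSE]
  }
  if (schema == "expression") {
    if (any(is.na(df$fpkm)) || any(df$fpkm < 0))
      stop("expression table: FPKM must be a non-negative number")
  }
  if (schema == "dea") {
    if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
      stop("dea table: padj must lie in [0, 1]")
  }
  if (schema == "splicing") {
    if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
      stop("splicing table: fdr must lie in [0, 1]")
  }
  if (schema == "disease") {
    if (any(is.na(df$linked)) || !all(df$linked %in% c(0, 1)))
      stop("disease table: 'linked' must be 0 or 1")
    df$linked <- as.logical(df$linked)
  }
  rownames(df) <- NULL
  df
}

#' Write a table deterministically
#'
#' Writes a data.frame as TSV with a header, doubles rendered at 6
#' significant digits and rows in canonical order (stable sort on the
#' identifier columns). Two writes of the same object are byte-identical.
#'
#' @param x data.frame.
#' @param path destination path.
#' @param sortBy columns to sort by before writing; defaults to the leading
#'   identifier column(s) present among `term_id`, `supermodule_id`, `gene`,
#'   `p1`. Use `NULL` to keep the input order.
#' @return `path`, invisibly.
#' @export
writeTable <- function(x, path,
                       sortBy = intersect(c("term_id", "supermodule_id",
                                            "gene", "p1"), names(x))) {
  stopifnot(is.data.frame(x))
  if (length(sortBy)) {
    keys <- lapply(sortBy, function(cl) x[[cl]])
    extra <- setdiff(c("term_a", "term_b", "p2"), sortBy)
    keys <- c(keys, lapply(intersect(extra, names(x)),
                           function(cl) x[[cl]]))
    x <- x[do.call(order, keys), , drop = FALSE]
  }
  cells <- vapply(x, formatCell, character(nrow(x)))
  if (nrow(x) == 1L) cells <- matrix(cells, nrow = 1L)
  if (nrow(x) == 0L)
    body <- character(0)
  else
    body <- apply(cells, 1L, paste, collapse = "\t")
  con <- file(path, open = "wb")  # binary: fixed "\n" EOL on every platform
  on.exit(close(con))
  writeLines(c(paste(names(x), collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}

#' Serialise pipeline objects to their TSV reports
#'
#' `writeReport` dispatches on the object type: an [ImpactReport-class]
#' produces `impact.tsv`-style rows (sorted by module id), a
#' [ModuleLibrary-class] produces `modules.tsv` rows (term, name, size,
#' component count, comma-joined sorted node list) and a data.frame is
#' written as-is via [writeTable()]. An empty library yields a header-only
#' file.
#'
#' @param x object to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
setGeneric("writeReport", function(x, path) standardGeneric("writeReport"))

#' @rdname writeReport
#' @export
setMethod("writeReport", "data.frame", function(x, path)
  writeTable(x, path))

#' @rdname writeReport
#' @export
setMethod("writeReport", "ImpactReport", function(x, path)
  writeTable(x@scores, path))

#' @rdname writeReport
#' @export
setMethod("writeReport", "ModuleLibrary", function(x, path) {
  df <- data.frame(
    term_id = vapply(x@modules, termId, character(1)),
    term_name = vapply(x@modules, termName, character(1)),
    size = vapply(x@modules, moduleSize, integer(1)),
    n_components = vapply(x@modules, function(m) length(m@components),
                          integer(1)),
    nodes = vapply(x@modules, function(m)
      paste(sort(m@nodes), collapse = ","), character(1)))
  rownames(df) <- NULL
  writeTable(df, path)
})

#' @rdname writeReport
#' @export
setMethod("writeReport", "SuperModuleSet", function(x, path) {
  df <- data.frame(
    supermodule_id = x@ids,
    members = vapply(x@members, paste, character(1), collapse = ","),
    n_modules = lengths(x@members),
    n_nodes = lengths(x@nodes))
  rownames(df) <- NULL
  writeTable(df, path)
})
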