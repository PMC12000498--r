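# featureCounts emits annotation columns before the per-sample counts; they
# are recognized by name and dropped on read (D: organism-agnostic, gene ids
# are opaque strings).
FEATURECOUNTS_ANNOT <- c("Chr", "Start", "End", "Strand", "Length")

#' Read a gene x sample count matrix from TSV
#'
#' Column 1 must be the gene identifier (any name; conventionally `gene_id`
#' or featureCounts' `Geneid`); remaining columns are per-sample counts.
#' featureCounts annotation columns (Chr, Start, End, Strand, Length) are
#' ignored by name.  Duplicated ids, negative values and fractional values
#' are errors, reported with the offending gene/cell.
#'
#' @param path path to a tab-separated file.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("read_counts: file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_counts: need a gene id column plus >=1 sample column")
  gene_ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  df <- df[, !(names(df) %in% FEATURECOUNTS_ANNOT), drop = FALSE]
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stop("read_counts: non-numeric values in sample column '", names(df)[j], "'")
  }
  m <- as.matrix(df)
  rownames(m) <- gene_ids
  count_matrix(m)
}

#' Write a count matrix to TSV
#' @param counts a [count_matrix()] (or compatible matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(unclass(counts)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Expects header columns `sample_id,population,assay,condition,replicate`.
#' Assay and condition are case-normalized; unknown assay values are errors.
#'
#' @param path path to a CSV file.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("read_sample_sheet: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  sample_sheet(df)
}

#' Write a sample sheet to CSV
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(unclass(sheet)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a rooted hierarchy tree
#'
#' Edge-list format is a two-column TSV (parent, child), with or without a
#' header line.  Newick format is parsed with \pkg{ape}; internal node labels
#' are required since they name populations, and branch lengths are ignored.
#'
#' @param path input path.
#' @param format `"edge_list"` or `"newick"`.
#' @return a [hierarchy_tree()].
#' @export
read_tree <- function(path, format = c("edge_list", "newick")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_tree: file not found: ", path)
  if (format == "edge_list") {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2) stop("read_tree: edge list needs two columns")
    if (identical(tolower(df[1, 1]), "parent")) df <- df[-1, , drop = FALSE]
    return(hierarchy_tree(df[, 1:2]))
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  hierarchy_tree(parse_newick_edges(txt))
}

# Minimal recursive-descent newick parser for rooted population trees.
# Internal nodes must be labelled (they name populations) and singleton
# chains like (((Thy)BCSP)pBCSP)SSC; are valid — which is why this is not
# delegated to a phylogenetics package: singleton internal nodes break the
# usual tip/internal numbering assumptions.  Branch lengths are ignored.
parse_newick_edges <- function(txt) {
  txt <- gsub("\\s", "", txt)
  if (!grepl(";$", txt)) stop("read_tree: newick must end with ';'")
  txt <- sub(";$", "", txt)
  pos <- 1L
  n <- nchar(txt)
  peek <- function() if (pos <= n) substr(txt, pos, pos) else ""
  read_label <- function() {
    start <- pos
    while (pos <= n && !substr(txt, pos, pos) %in% c("(", ")", ",", ":"))
      pos <<- pos + 1L
    lab <- substr(txt, start, pos - 1L)
    if (peek() == ":") {                   # skip branch length
      pos <<- pos + 1L
      while (pos <= n && grepl("[-0-9.eE+]", substr(txt, pos, pos)))
        pos <<- pos + 1L
    }
    lab
  }
  edges <- list()
  node_id <- 0L
  parse_clade <- function() {
    children <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children <- c(children, parse_clade())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("read_tree: malformed newick near position ", pos)
      }
    }
    lab <- read_label()
    if (!nzchar(lab)) {
      if (length(children))
        stop("read_tree: newick internal nodes must be labelled")
      stop("read_tree: empty leaf label in newick")
    }
    for (ch in children)
      edges[[length(edges) + 1L]] <<- c(lab, ch)
    lab
  }
  parse_clade()
  if (pos <= n) stop("read_tree: trailing characters in newick")
  if (!length(edges)) stop("read_tree: newick contains a single node, no edges")
  out <- do.call(rbind, edges)
  data.frame(parent = out[, 1], child = out[, 2], stringsAsFactors = FALSE)
}

#' Write a hierarchy tree as a two-column TSV edge list
#' @param tree a [hierarchy_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  utils::write.table(tree$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member gene ids.
#'
#' @param path path to a .gmt file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3)
  if (length(bad))
    stop("read_gmt: line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- mapply(function(name, desc, members)
    paste(c(name, desc, members), collapse = "\t"),
    names(collection), descriptions, collection)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a result table as commented TSV
#'
#' All pipeline result tables share one dialect: `# key=value` comment lines
#' carrying the run parameters, then a header row and tab-separated data.
#' Diff-able and round-trippable via [read_result_tsv()].
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list echoed into `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s=%s", k, paste(format(params[[k]], digits = 15),
                                           collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented result TSV written by [write_result_tsv()]
#' @param path input path.
#' @return data.frame with attribute `params` (named character vector).
#' @export
read_result_tsv <- function(path) {
  if (!file.exists(path)) stop("read_result_tsv: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  kv <- sub("^#\\s*", "", hdr)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  params <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  attr(df, "params") <- params
  df
}
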