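# File formats: tab-separated tables with '#' metadata headers, and newick
# trees. TSV dialect: header row, UTF-8, '.' decimal separator; every file
# written by a pipeline stage starts with comment lines recording the tool
# version, producing stage, config hash and seed.

# tiny polynomial hash over the deparsed config -- enough to fingerprint a run
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a table as TSV with a metadata comment header
#'
#' @param x data.frame.
#' @param path output file.
#' @param stage producing stage name recorded in the header.
#' @param seed seed recorded in the header (may be `NA`).
#' @param config optional object hashed into the header.
#' @return `path`, invisibly.
#' @export
write_tsv_stage <- function(x, path, stage = "unknown", seed = NA, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sodalake %s", .sodalake_version()),
    sprintf("# stage: %s", stage),
    sprintf("# config_hash: %s", if (is.null(config)) "none" else config_hash(config)),
    sprintf("# seed: %s", as.character(seed))), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_stage()] (or any plain TSV)
#'
#' '#'-prefixed lines are treated as comments.
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv_stage <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a rooted phylogeny from a newick file
#'
#' Wraps [ape::read.tree()] with validation: branch lengths must be present
#' and nonnegative, and every leaf must carry a unique label.
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  stop_if(is.null(tree), "could not parse newick file")
  stop_if(is.null(tree$edge.length), "tree has no branch lengths")
  stop_if(any(tree$edge.length < 0), "tree has negative branch lengths")
  stop_if(any(!nzchar(tree$tip.label)), "tree has unlabeled leaves")
  stop_if(anyDuplicated(tree$tip.label) > 0, "tree has duplicate leaf labels")
  tree
}

#' Write a phylogeny to newick
#'
#' Branch lengths are serialized with 10 significant digits so a read/write
#' round trip preserves them.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stop_if(!inherits(tree, "phylo"), "tree must be a 'phylo' object")
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
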