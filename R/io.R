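#' @include AllClasses.R
NULL

# logging: structured messages to stderr, gated by options(rejunet.log_level)
.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

.log <- function(level, ...) {
  thr <- getOption("rejunet.log_level", "info")
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[thr]])
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  invisible(NULL)
}

.read_tsv <- function(path, header = TRUE) {
  utils::read.delim(path, header = header, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    dec = ".", comment.char = "", quote = "")
}

#' Read a sparse count matrix with sidecar files
#'
#' Loads a Matrix Market coordinate file together with its gene, barcode and
#' cell-metadata sidecars into a \linkS4class{CellMatrix}. Gene files may
#' carry one column (symbol) or the cellranger two-column form (id, symbol),
#' in which case the second column is used. Duplicate gene symbols are
#' resolved by keeping the row with the larger total count; the collision is
#' logged. Cells missing from the metadata table are rejected.
#'
#' @param mtx_path Matrix Market (.mtx) coordinate file, genes x cells.
#' @param genes_path TSV of gene symbols, one row per matrix row.
#' @param barcodes_path TSV of cell barcodes, one row per matrix column.
#' @param meta_path TSV keyed by a \code{barcode} column, with columns
#'   \code{cell_type}, \code{condition}, \code{replicate} (optional
#'   \code{sex}).
#' @return A \linkS4class{CellMatrix}.
#' @seealso [writeCellMatrix()]
#' @export
readCellMatrix <- function(mtx_path, genes_path, barcodes_path, meta_path) {
  m <- Matrix::readMM(mtx_path)
  if (any(m@x != round(m@x)) || any(m@x < 0))
    stop("non-integer or negative counts in ", mtx_path)
  g <- .read_tsv(genes_path, header = FALSE)
  genes <- if (ncol(g) >= 2) as.character(g[[2]]) else as.character(g[[1]])
  bc <- .read_tsv(barcodes_path, header = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop("matrix declares ", nrow(m), " genes but ", genes_path,
         " lists ", length(genes))
  if (ncol(m) != length(bc))
    stop("matrix declares ", ncol(m), " cells but ", barcodes_path,
         " lists ", length(bc))
  dimnames(m) <- list(genes, as.character(bc))
  m <- .dedupe_genes(m)
  meta <- .read_tsv(meta_path)
  if (!"barcode" %in% colnames(meta))
    stop("metadata file ", meta_path, " needs a 'barcode' column")
  rownames(meta) <- meta$barcode
  CellMatrix(m, meta[setdiff(colnames(meta), "barcode")])
}

# keep the duplicate row with the larger total count
.dedupe_genes <- function(m) {
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  if (!length(dup)) return(m)
  .log("warn", "duplicate gene symbols resolved by larger total count: ",
       paste(dup, collapse = ", "))
  tot <- Matrix::rowSums(m)
  keep <- unlist(lapply(split(seq_len(nrow(m)), rownames(m)),
                        function(i) i[which.max(tot[i])]))
  m[sort(unname(keep)), , drop = FALSE]
}

#' Write a CellMatrix to Matrix Market plus sidecars
#'
#' Inverse of [readCellMatrix()]; a write-then-read round trip restores
#' bit-identical counts.
#'
#' @param x A \linkS4class{CellMatrix}.
#' @param dir Output directory (created if needed). Files written:
#'   \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv},
#'   \code{cell_meta.tsv}.
#' @return The directory, invisibly.
#' @export
writeCellMatrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(x, "counts")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "genes.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  meta <- as.data.frame(SummarizedExperiment::colData(x))
  meta <- cbind(barcode = colnames(x), meta)
  utils::write.table(meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

.SIGN_TOKENS <- c("1" = 1, "+1" = 1, "+" = 1, "activation" = 1,
                  "activates" = 1, "stimulation" = 1,
                  "-1" = -1, "-" = -1, "inhibition" = -1,
                  "inhibits" = -1, "repression" = -1)

.parse_signs <- function(tok, path) {
  key <- tolower(trimws(as.character(tok)))
  s <- .SIGN_TOKENS[key]
  if (anyNA(s)) {
    bad <- which(is.na(s))[1]
    stop("unknown sign token '", tok[bad], "' at data line ", bad,
         " of ", path)
  }
  unname(s)
}

#' Read a signed edge list
#'
#' Accepts either a headered 3-column TSV (\code{source}, \code{target},
#' \code{sign}) or the SIF dialect (\code{source relation target}, no
#' header). Signs may be encoded numerically (+1/-1) or as tokens such as
#' \code{activation}/\code{inhibition}. Exact duplicate interactions are
#' filtered out; an unparseable sign is an error naming the line.
#'
#' @param path Path to the edge file.
#' @return An \linkS4class{EdgeList}.
#' @export
readEdgeList <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  headered <- all(c("source", "target", "sign") %in% tolower(trimws(first)))
  d <- .read_tsv(path, header = headered)
  if (nrow(d) == 0L) {
    .log("warn", "empty edge file: ", path)
    return(EdgeList())
  }
  if (headered) {
    colnames(d) <- tolower(colnames(d))
    EdgeList(d$source, d$target, .parse_signs(d$sign, path))
  } else {
    if (ncol(d) != 3L)
      stop("SIF-dialect edge file must have 3 columns: ", path)
    EdgeList(d[[1]], d[[3]], .parse_signs(d[[2]], path))
  }
}

#' Write an edge list as headered TSV
#'
#' @param x An \linkS4class{EdgeList}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  utils::write.table(edges(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# canonical DE column names and accepted aliases
.DE_ALIASES <- list(
  gene = c("gene", "genes", "symbol", "feature"),
  avg_log_fc = c("avg_log_fc", "avg_log2fc", "avg_logfc", "log_fc", "logfc",
                 "log2foldchange", "lfc"),
  p_adj = c("p_adj", "padj", "p_val_adj", "adj_p", "fdr", "qvalue"),
  pct_cond1 = c("pct_cond1", "pct.1", "pct_1", "pct1"),
  pct_cond2 = c("pct_cond2", "pct.2", "pct_2", "pct2"))

#' Read a differential-expression table
#'
#' Reads a per-cell-type DE table with columns \code{gene},
#' \code{avg_log_fc}, \code{p_adj}, \code{pct_cond1}, \code{pct_cond2}.
#' Common aliases (\code{padj}, \code{avg_log2FC}, \code{pct.1}, ...) are
#' recognised; further aliases can be supplied. A missing required column is
#' an error listing the columns actually found.
#'
#' @param path TSV path.
#' @param aliases optional named list extending the built-in alias map
#'   (canonical name -> character vector of accepted headers).
#' @return data.frame with the canonical columns.
#' @export
readDETable <- function(path, aliases = list()) {
  d <- .read_tsv(path)
  if (nrow(d) == 0L) .log("warn", "empty DE table: ", path)
  amap <- .DE_ALIASES
  for (nm in names(aliases)) amap[[nm]] <- union(amap[[nm]], aliases[[nm]])
  lc <- tolower(colnames(d))
  out <- lapply(names(amap), function(canon) {
    hit <- which(lc %in% tolower(amap[[canon]]))
    if (!length(hit)) return(NULL)
    d[[hit[1]]]
  })
  names(out) <- names(amap)
  missing <- names(amap)[vapply(out, is.null, logical(1))]
  if (length(missing))
    stop("DE table ", path, " lacks required column(s) ",
         paste(missing, collapse = ", "), "; found: ",
         paste(colnames(d), collapse = ", "))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$gene <- as.character(out$gene)
  out
}

#' Write a differential-expression table
#'
#' @param x data.frame with the canonical DE columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeDETable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signaling-intermediate score table
#'
#' Two-column TSV (\code{molecule}, \code{score}); scores are activity
#' values in [0, 1] as produced by an upstream signaling hotspot tool.
#' \code{NA} entries are preserved as missing values -- they carry meaning
#' for the differential-activity rule and are never imputed.
#'
#' @param path TSV path.
#' @return Named numeric vector of scores (possibly with \code{NA}s).
#' @export
readScoreTable <- function(path) {
  d <- .read_tsv(path)
  if (nrow(d) == 0L) {
    .log("warn", "empty score table: ", path)
    return(stats::setNames(numeric(), character()))
  }
  lc <- tolower(colnames(d))
  mcol <- which(lc %in% c("molecule", "gene", "symbol"))[1]
  scol <- which(lc %in% c("score", "activity"))[1]
  if (is.na(mcol) || is.na(scol))
    stop("score table ", path, " needs 'molecule' and 'score' columns; ",
         "found: ", paste(colnames(d), collapse = ", "))
  s <- suppressWarnings(as.numeric(d[[scol]]))
  stats::setNames(s, as.character(d[[mcol]]))
}

#' Write a score table
#'
#' @param scores named numeric vector (NAs allowed).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeScoreTable <- function(scores, path) {
  utils::write.table(
    data.frame(molecule = names(scores), score = unname(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor scaffold
#'
#' TSV with columns \code{ligand} and \code{receptor} (optional logical
#' \code{secreted} flag). Duplicate pairs are dropped.
#'
#' @param path TSV path.
#' @return data.frame with columns ligand, receptor (and secreted if given).
#' @export
readScaffold <- function(path) {
  d <- .read_tsv(path)
  colnames(d) <- tolower(colnames(d))
  if (!all(c("ligand", "receptor") %in% colnames(d)))
    stop("scaffold ", path, " needs 'ligand' and 'receptor' columns; found: ",
         paste(colnames(d), collapse = ", "))
  d <- d[!duplicated(d[c("ligand", "receptor")]), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read gene-set collections in GMT format
#'
#' One set per line: name, description, then tab-separated member symbols.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields in ", path)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1L))
}

#' Read pipeline configuration from YAML or JSON
#'
#' Recognised keys map onto \linkS4class{PipelineConfig} fields; any other
#' key is collected verbatim into \code{passthrough} (settings for upstream
#' tools such as the signaling hotspot cutoff/percentile).
#'
#' @param path \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- setdiff(names(formals(PipelineConfig)), "passthrough")
  args <- vals[intersect(names(vals), known)]
  extra <- vals[setdiff(names(vals), known)]
  pt <- if (!is.null(extra$passthrough)) extra$passthrough else list()
  extra$passthrough <- NULL
  args$passthrough <- c(pt, extra)
  do.call(PipelineConfig, args)
}
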