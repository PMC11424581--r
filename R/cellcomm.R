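#' @include AllClasses.R
NULL

.type_cells <- function(m, type) {
  ct <- SummarizedExperiment::colData(m)$cell_type
  if (!type %in% ct) stop("cell type '", type, "' absent from the matrix")
  which(ct == type)
}

.expr_mean <- function(m, gene, cells) {
  if (!gene %in% rownames(m)) stop("gene '", gene, "' absent from the matrix")
  v <- SummarizedExperiment::assay(m, "counts")[gene, cells]
  v <- as.numeric(v)
  expressing <- v[v > 0]
  if (!length(expressing)) return(0)
  mean(expressing)
}

#' Ligand-receptor interaction score
#'
#' The product of the mean ligand expression over sender-type cells that
#' express the ligand and the mean receptor expression over receiver-type
#' cells that express the receptor ("expressing" meaning count > 0). If
#' either expressing set is empty the score is 0.
#'
#' @param m A \linkS4class{CellMatrix}.
#' @param sender_type,receiver_type cell types present in \code{m}.
#' @param ligand,receptor gene symbols present in the matrix.
#' @return Non-negative numeric score.
#' @export
interactionScore <- function(m, sender_type, receiver_type, ligand,
                             receptor) {
  lm_ <- .expr_mean(m, ligand, .type_cells(m, sender_type))
  rm_ <- .expr_mean(m, receptor, .type_cells(m, receiver_type))
  lm_ * rm_
}

#' Score a ligand-receptor scaffold across cell-type pairs
#'
#' Computes the interaction score of every scaffold pair for every ordered
#' (sender, receiver) cell-type combination, then assigns a significance
#' within each stratum with [interactionSignificance()].
#'
#' @param m A \linkS4class{CellMatrix}.
#' @param scaffold data.frame with columns \code{ligand}, \code{receptor}
#'   (see [readScaffold()]).
#' @param condition label copied into the records (defaults to the
#'   matrix's single condition value).
#' @param keep_records optional data.frame of (sender_type, receiver_type,
#'   ligand, receptor) keys to retain, e.g. an externally computed
#'   receptor-TF compatibility list; \code{NULL} keeps everything.
#' @return data.frame of interaction records: \code{sender_type},
#'   \code{receiver_type}, \code{ligand}, \code{receptor}, \code{score},
#'   \code{significance}, \code{significant}, \code{condition}.
#' @export
scoreInteractions <- function(m, scaffold, condition = NULL,
                              keep_records = NULL) {
  types <- sort(unique(SummarizedExperiment::colData(m)$cell_type))
  if (is.null(condition)) {
    cond <- unique(SummarizedExperiment::colData(m)$condition)
    condition <- if (length(cond) == 1L) cond else "mixed"
  }
  combos <- expand.grid(sender_type = types, receiver_type = types,
                        stringsAsFactors = FALSE)
  cnt <- SummarizedExperiment::assay(m, "counts")
  ct <- SummarizedExperiment::colData(m)$cell_type
  # per-type expressing means for all scaffold genes at once
  genes <- unique(c(scaffold$ligand, scaffold$receptor))
  absent <- setdiff(genes, rownames(cnt))
  if (length(absent))
    stop("gene '", absent[1], "' absent from the matrix")
  emeans <- vapply(types, function(tp) {
    sub <- cnt[genes, ct == tp, drop = FALSE]
    pos <- Matrix::rowSums(sub > 0)
    ifelse(pos > 0, Matrix::rowSums(sub) / pos, 0)
  }, numeric(length(genes)))
  emeans <- matrix(emeans, nrow = length(genes),
                   dimnames = list(genes, types))
  rec <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    data.frame(sender_type = combos$sender_type[i],
               receiver_type = combos$receiver_type[i],
               ligand = scaffold$ligand, receptor = scaffold$receptor,
               score = emeans[scaffold$ligand, combos$sender_type[i]] *
                 emeans[scaffold$receptor, combos$receiver_type[i]],
               stringsAsFactors = FALSE)
  }))
  rec$condition <- condition
  if (!is.null(keep_records)) {
    key <- function(d) paste(d$sender_type, d$receiver_type, d$ligand,
                             d$receptor, sep = "\r")
    rec <- rec[key(rec) %in% key(keep_records), , drop = FALSE]
  }
  rownames(rec) <- NULL
  interactionSignificance(rec)
}

#' Percentile significance of interaction scores
#'
#' Within each (sender, receiver) stratum, the significance of a record is
#' the fraction of the stratum's scaffold scores strictly below its own
#' (ties share the lower rank). Records in the top decile (significance at
#' least 0.90) are flagged significant; when all scores tie, none is.
#'
#' @param records data.frame of scored interaction records.
#' @return The records with \code{significance} and \code{significant}
#'   columns (re)computed.
#' @export
interactionSignificance <- function(records) {
  stopifnot(nrow(records) >= 1L)
  stratum <- paste(records$sender_type, records$receiver_type, sep = "\r")
  sig <- numeric(nrow(records))
  for (s in unique(stratum)) {
    i <- which(stratum == s)
    sc <- records$score[i]
    sig[i] <- vapply(sc, function(x) sum(sc < x), numeric(1)) / length(sc)
  }
  records$significance <- sig
  records$significant <- sig >= 0.90
  records
}

.rec_key <- function(d) paste(d$sender_type, d$receiver_type, d$ligand,
                              d$receptor, sep = "\r")

#' Interactions unique to the treated condition
#'
#' Keeps treated-condition records with a significance strictly above
#' \code{cutoff} (the top decile) whose (sender, receiver, ligand,
#' receptor) key is not significant in the control condition. A channel
#' present but non-significant in control still counts as treated-unique.
#' Records tied exactly at the cutoff are logged.
#'
#' @param treated,control record data.frames from [scoreInteractions()].
#' @param cutoff significance cutoff (strict), default 0.90.
#' @return data.frame of treated-unique records.
#' @export
treatedUnique <- function(treated, control, cutoff = 0.90) {
  ties <- which(treated$significance == cutoff)
  if (length(ties))
    .log("info", length(ties), " treated record(s) tied exactly at the ",
         cutoff, " significance cutoff are excluded")
  ctrl_sig <- .rec_key(control[control$significant, , drop = FALSE])
  out <- treated[treated$significance > cutoff &
                   !.rec_key(treated) %in% ctrl_sig, , drop = FALSE]
  rownames(out) <- NULL
  out
}
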