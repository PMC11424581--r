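#' @include AllClasses.R
NULL

# splittable seeding: one global seed plus an operation tag gives every
# generator its own stream, so adding a generator never perturbs another's
# fixtures; result kept below 2^31
.childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulate a planted regulatory network
#'
#' Builds a rooted out-tree prior network whose root is the planted master
#' regulator: TF nodes form the upper levels (all edges between TFs
#' activate, so every TF is active when the root is), target genes are
#' leaves reached by activating or -- with probability
#' \code{inhibitor_fraction} -- inhibiting edges. The Boolean profile is the
#' forward simulation of activating the root under inhibition-dominant
#' logic, after which \code{noise_fraction} of the non-root nodes have
#' their state flipped. The tree is fully hierarchical (Krackhardt
#' hierarchy 1) and, at zero noise, the root's activation explains every
#' node state.
#'
#' @param n_tfs number of TF (internal) nodes, >= 1.
#' @param n_targets number of leaf target genes.
#' @param branching maximum out-degree, default 2; \code{n_tfs} must
#'   provide enough parent capacity.
#' @param inhibitor_fraction probability that a TF-to-target edge inhibits.
#' @param noise_fraction fraction of non-root nodes whose profile state is
#'   flipped (rounded to a count).
#' @param seed integer seed.
#' @return A \linkS4class{PlantedNetwork}.
#' @examples
#' pn <- simulatePlantedTRN(n_tfs = 3, n_targets = 4, seed = 1)
#' explainedFraction(pn)  # 1 at zero noise
#' @export
simulatePlantedTRN <- function(n_tfs, n_targets, branching = 2,
                               inhibitor_fraction = 0.2, noise_fraction = 0,
                               seed = 1L) {
  stopifnot(n_tfs >= 1, n_targets >= 0, branching >= 1,
            inhibitor_fraction >= 0, inhibitor_fraction <= 1,
            noise_fraction >= 0, noise_fraction <= 1)
  n <- n_tfs + n_targets
  if (ceiling((n - 1) / branching) > n_tfs)
    stop(n_tfs, " TFs with branching ", branching,
         " cannot parent ", n - 1, " children")
  set.seed(.childSeed(seed, "planted_trn"))
  wd <- nchar(as.character(n))
  tf_names <- sprintf(paste0("TF%0", wd, "d"), seq_len(n_tfs))
  tg_names <- sprintf(paste0("G%0", wd, "d"), seq_len(n_targets))
  children <- c(tf_names[-1], tg_names)
  parent <- tf_names[ceiling(seq_along(children) / branching)]
  sign <- ifelse(children %in% tg_names &
                   stats::runif(length(children)) < inhibitor_fraction,
                 -1, 1)
  pkn <- EdgeList(parent, children, sign)

  # forward simulation: all TFs active, leaves follow their edge sign
  state <- stats::setNames(rep(1L, n), c(tf_names, tg_names))
  state[children[sign == -1]] <- 0L

  profile <- state
  n_flip <- round(noise_fraction * (n - 1))
  if (n_flip > 0) {
    flip <- sample(setdiff(names(state), tf_names[1]), n_flip)
    profile[flip] <- 1L - profile[flip]
  }
  methods::new("PlantedNetwork", pkn = pkn,
               profile = BooleanProfile(profile),
               planted_mr = tf_names[1],
               explained_fraction = mean(profile == state))
}

#' Simulate single-cell counts with planted differential expression
#'
#' Draws negative-binomial counts for two conditions (treated vs control)
#' with a multiplicative condition effect of \code{2^lfc} on each cell
#' type's planted DE genes, followed by independent dropout. The returned
#' per-type DE tables are computed from the generating parameters (the
#' planted truth), not re-estimated: \code{avg_log_fc} is the planted log2
#' fold change and the \code{pct} columns are the expected detection
#' fractions \eqn{(1 - dropout) \cdot P(\mathrm{count} > 0)}.
#'
#' @param cell_types character vector of cell-type names.
#' @param n_cells_per_type cells per type per condition.
#' @param de_genes_per_type planted DE genes per cell type.
#' @param n_housekeeping shared non-DE genes.
#' @param lfc planted log2 fold change of DE genes (treated over control).
#' @param base_mu control-condition negative-binomial mean.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param dropout independent zeroing probability.
#' @param seed integer seed.
#' @return List with \code{matrix} (a \linkS4class{CellMatrix} holding both
#'   conditions) and \code{de_tables} (named list of truth DE data.frames,
#'   one per cell type, covering all genes).
#' @export
simulateCounts <- function(cell_types = c("Tcell", "Fibroblast"),
                           n_cells_per_type = 50, de_genes_per_type = 5,
                           n_housekeeping = 20, lfc = 1, base_mu = 5,
                           nb_dispersion = 0.4, dropout = 0.2, seed = 1L) {
  set.seed(.childSeed(seed, "counts"))
  hk <- sprintf("HK%03d", seq_len(n_housekeeping))
  de_sets <- stats::setNames(lapply(seq_along(cell_types), function(i)
    sprintf("%s_DE%02d", cell_types[i], seq_len(de_genes_per_type))),
    cell_types)
  genes <- c(hk, unlist(de_sets, use.names = FALSE))
  conds <- c("treated", "control")
  meta <- expand.grid(cell = seq_len(n_cells_per_type),
                      cell_type = cell_types, condition = conds,
                      stringsAsFactors = FALSE)
  barcodes <- sprintf("%s_%s_c%03d", meta$cell_type, meta$condition,
                      meta$cell)
  rdraw <- function(n, mu) {
    if (nb_dispersion > 0) stats::rnbinom(n, mu = mu, size = 1 / nb_dispersion)
    else stats::rpois(n, mu)
  }
  counts <- matrix(0L, length(genes), nrow(meta),
                   dimnames = list(genes, barcodes))
  for (j in seq_len(nrow(meta))) {
    mu <- rep(base_mu, length(genes))
    if (meta$condition[j] == "treated") {
      idx <- genes %in% de_sets[[meta$cell_type[j]]]
      mu[idx] <- base_mu * 2^lfc
    }
    x <- rdraw(length(genes), mu)
    x[stats::runif(length(x)) < dropout] <- 0L
    counts[, j] <- x
  }
  cm <- CellMatrix(counts,
                   data.frame(row.names = barcodes,
                              cell_type = meta$cell_type,
                              condition = meta$condition, replicate = 1L))
  p_pos <- function(mu) {
    p0 <- if (nb_dispersion > 0)
      stats::dnbinom(0, mu = mu, size = 1 / nb_dispersion)
    else stats::dpois(0, mu)
    (1 - dropout) * (1 - p0)
  }
  de_tables <- lapply(cell_types, function(ct) {
    is_de <- genes %in% de_sets[[ct]]
    g_lfc <- ifelse(is_de, lfc, 0)
    data.frame(gene = genes, avg_log_fc = g_lfc,
               p_adj = ifelse(is_de & lfc != 0, 1e-6, 1),
               pct_cond1 = p_pos(base_mu * 2^g_lfc),
               pct_cond2 = p_pos(base_mu),
               stringsAsFactors = FALSE)
  })
  list(matrix = cm, de_tables = stats::setNames(de_tables, cell_types))
}

#' Simulate signaling-intermediate score tables
#'
#' Plants \code{n_differential} truly differential molecules (treated
#' activity uniform on (0.70, 1], control uniform on [0, 0.30)) among
#' decoys that are either mid-range in both conditions or missing
#' (\code{NA}) in one of them.
#'
#' @param n_molecules total molecules.
#' @param n_differential planted differential molecules.
#' @param seed integer seed.
#' @return List with \code{treated} and \code{control} named score vectors
#'   and \code{truth}, the planted molecule set.
#' @export
simulateIntermediateTables <- function(n_molecules = 100,
                                       n_differential = 10, seed = 1L) {
  stopifnot(n_differential <= n_molecules)
  set.seed(.childSeed(seed, "intermediates"))
  mol <- sprintf("MOL%04d", seq_len(n_molecules))
  truth <- sort(sample(mol, n_differential))
  treated <- stats::setNames(stats::runif(n_molecules, 0.35, 0.65), mol)
  control <- stats::setNames(stats::runif(n_molecules, 0.35, 0.65), mol)
  decoys <- setdiff(mol, truth)
  kind <- sample(c("mid", "na_treated", "na_control"), length(decoys),
                 replace = TRUE)
  treated[decoys[kind == "na_treated"]] <- NA_real_
  control[decoys[kind == "na_control"]] <- NA_real_
  treated[truth] <- stats::runif(length(truth), 0.70 + 1e-9, 1)
  control[truth] <- stats::runif(length(truth), 0, 0.30 - 1e-9)
  list(treated = treated, control = control, truth = truth)
}

#' Simulate a ligand-receptor communication experiment
#'
#' Builds a scaffold of ligand-receptor pairs, a treated and a control
#' count matrix over the given cell types, and plants
#' \code{planted_unique} channels whose ligand (in the sender type) and
#' receptor (in the receiver type) are strongly expressed only in the
#' treated matrix -- by construction far above the decoy score scale, so
#' they land in the top decile of their stratum. Decoy gene counts are
#' drawn once and shared verbatim between conditions, so decoy channels
#' rank identically in both and never appear treated-unique.
#'
#' @param cell_types character vector (>= 2 recommended) of cell types.
#' @param scaffold_size number of ligand-receptor pairs.
#' @param planted_unique number of planted treated-only channels.
#' @param n_cells_per_type cells per type in each matrix.
#' @param seed integer seed.
#' @return List with \code{treated} and \code{control}
#'   \linkS4class{CellMatrix} objects, \code{scaffold} (data.frame ligand,
#'   receptor) and \code{truth} (data.frame sender_type, receiver_type,
#'   ligand, receptor).
#' @export
simulateLRExperiment <- function(cell_types = c("Macrophage", "Fibroblast"),
                                 scaffold_size = 60, planted_unique = 3,
                                 n_cells_per_type = 20, seed = 1L) {
  stopifnot(planted_unique <= scaffold_size, length(cell_types) >= 1)
  set.seed(.childSeed(seed, "lr"))
  lig <- sprintf("LIG%03d", seq_len(scaffold_size))
  rec <- sprintf("REC%03d", seq_len(scaffold_size))
  scaffold <- data.frame(ligand = lig, receptor = rec,
                         stringsAsFactors = FALSE)
  genes <- c(lig, rec)
  meta <- expand.grid(cell = seq_len(n_cells_per_type),
                      cell_type = cell_types, stringsAsFactors = FALSE)
  mk_meta <- function(cond) data.frame(
    row.names = sprintf("%s_%s_c%03d", meta$cell_type, cond, meta$cell),
    cell_type = meta$cell_type, condition = cond, replicate = 1L)
  base <- matrix(stats::rpois(length(genes) * nrow(meta), 0.8),
                 length(genes), nrow(meta), dimnames = list(genes, NULL))
  type_pairs <- expand.grid(sender = cell_types, receiver = cell_types,
                            stringsAsFactors = FALSE)
  planted_rows <- sample(scaffold_size, planted_unique)
  planted_pair <- type_pairs[sample(nrow(type_pairs), planted_unique,
                                    replace = TRUE), , drop = FALSE]
  # planted genes are silent everywhere except the planted population in the
  # treated matrix, so the channel is unique to its sender/receiver stratum
  base[c(lig[planted_rows], rec[planted_rows]), ] <- 0L
  treated <- base
  for (i in seq_len(planted_unique)) {
    r <- planted_rows[i]
    send_cols <- meta$cell_type == planted_pair$sender[i]
    recv_cols <- meta$cell_type == planted_pair$receiver[i]
    treated[lig[r], send_cols] <- stats::rpois(sum(send_cols), 30) + 10L
    treated[rec[r], recv_cols] <- stats::rpois(sum(recv_cols), 30) + 10L
  }
  meta_t <- mk_meta("treated")
  meta_c <- mk_meta("control")
  colnames(treated) <- rownames(meta_t)
  control <- base
  colnames(control) <- rownames(meta_c)
  truth <- data.frame(sender_type = planted_pair$sender,
                      receiver_type = planted_pair$receiver,
                      ligand = lig[planted_rows],
                      receptor = rec[planted_rows],
                      stringsAsFactors = FALSE)
  list(treated = CellMatrix(treated, meta_t),
       control = CellMatrix(control, meta_c),
       scaffold = scaffold,
       truth = truth[order(truth$ligand), , drop = FALSE])
}
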