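#' PSM-level reporter-intensity table
#'
#' @param df data.frame with columns `protein`, `peptide`, `psm_id`, `coiso`
#'   (co-isolation fraction, in `[0,1]`), `sn` (mean reporter S/N) and one
#'   column per reporter channel (intensities >= 0).
#' @param channels channel column names.
#' @return data.frame of class `psm_table`.
#' @export
psm_table <- function(df, channels) {
  need <- c("protein", "peptide", "psm_id", "coiso", "sn")
  miss <- setdiff(c(need, channels), names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$coiso < 0 | df$coiso > 1, na.rm = TRUE)) stop("coiso must be in [0,1]")
  for (ch in channels) {
    if (any(df[[ch]] < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  }
  structure(df, channels = channels, class = c("psm_table", "data.frame"))
}

#' Plex design table
#'
#' @param channel channel identifiers (must be >= 2 per kit).
#' @param kit kit (multiplex) identifier per channel.
#' @param sample sample label per channel.
#' @param group group label per channel.
#' @param is_bridge logical, bridge-sample flag; when any bridge is declared it
#'   must be present in every kit.
#' @return data.frame of class `plex_design`.
#' @export
plex_design <- function(channel, kit, sample, group = NA_character_,
                        is_bridge = FALSE) {
  out <- data.frame(channel = channel, kit = kit, sample = sample,
                    group = group, is_bridge = is_bridge)
  tab <- table(out$kit)
  if (any(tab < 2)) stop("each kit must have >= 2 channels")
  if (any(out$is_bridge)) {
    br_kits <- unique(out$kit[out$is_bridge])
    if (!setequal(br_kits, unique(out$kit))) {
      stop("declared bridge sample must be present in every kit")
    }
  }
  class(out) <- c("plex_design", "data.frame")
  out
}

#' Filter PSMs and aggregate to a protein matrix
#'
#' Keeps PSMs with co-isolation interference below `coiso_max` and mean
#' reporter S/N above `sn_min`, then sums reporter intensities per protein and
#' channel. Proteins with no passing PSM are absent from the output.
#'
#' @param table a [psm_table].
#' @param coiso_max co-isolation ceiling (default 0.5).
#' @param sn_min S/N floor (default 10).
#' @return protein x channel matrix (class `protein_matrix`), with the number
#'   of passing PSMs per protein in attribute `n_psms`.
#' @export
filter_aggregate_psms <- function(table, coiso_max = 0.5, sn_min = 10) {
  stopifnot(inherits(table, "psm_table"))
  if (coiso_max < 0 || coiso_max > 1) stop("coiso_max must be in [0,1]")
  channels <- attr(table, "channels")
  keep <- table$coiso < coiso_max & table$sn > sn_min
  d <- table[keep, , drop = FALSE]
  if (!nrow(d)) {
    m <- matrix(numeric(0), 0, length(channels),
                dimnames = list(NULL, channels))
    return(structure(m, n_psms = integer(0), class = c("protein_matrix", class(m))))
  }
  prots <- sort(unique(d$protein))
  m <- vapply(channels, function(ch) {
    vapply(split(d[[ch]], factor(d$protein, levels = prots)), sum, numeric(1))
  }, numeric(length(prots)))
  m <- matrix(m, nrow = length(prots), dimnames = list(prots, channels))
  structure(m, n_psms = as.integer(table(factor(d$protein, levels = prots))),
            class = c("protein_matrix", class(m)))
}

#' Channel loading normalization
#'
#' Each channel's total intensity is divided by the mean of all channels'
#' totals to form channel-specific loading factors; intensities are divided by
#' their channel's factor so every channel sums to the common mean. Idempotent.
#'
#' @param matrix protein x channel intensity matrix.
#' @return list with `matrix` (normalized) and `factors` (named per channel).
#' @export
loading_normalize <- function(matrix) {
  sums <- colSums(matrix)
  if (any(sums <= 0)) {
    stop("zero-sum channel(s): ", paste(colnames(matrix)[sums <= 0], collapse = ", "))
  }
  factors <- sums / mean(sums)
  out <- sweep(matrix, 2L, factors, "/")
  list(matrix = out, factors = factors)
}

#' Low-abundance resampling imputation
#'
#' Missing entries (NA or 0) are replaced by draws from the channel's observed
#' sub-`quantile` intensity distribution (empirical resampling, seeded).
#' Observed entries are untouched. This is a declared interpretation of
#' "low abundance resampling"; the interpretation is recorded in the
#' `imputation` attribute of the result.
#'
#' @param matrix protein x channel matrix with NA/0 for missing.
#' @param quantile sub-quantile defining "low abundance" (default 0.05).
#' @param seed integer seed (mandatory for reproducibility).
#' @return matrix with missing entries filled.
#' @export
impute_low_abundance <- function(matrix, quantile = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  out <- matrix
  for (j in seq_len(ncol(out))) {
    col <- out[, j]
    miss <- is.na(col) | col == 0
    obs <- col[!miss]
    if (!length(obs)) stop("channel fully missing: ", colnames(out)[j])
    if (!any(miss)) next
    cut <- stats::quantile(obs, quantile, names = FALSE)
    pool <- obs[obs <= cut]
    if (!length(pool)) pool <- min(obs)
    out[miss, j] <- sample(pool, sum(miss), replace = TRUE)
  }
  attr(out, "imputation") <- sprintf(
    "empirical resampling from bottom %g quantile per channel, seed %d",
    quantile, as.integer(seed))
  out
}

#' Log2 conversion and per-kit centering
#'
#' Intensities are log2-transformed and, per protein, the mean log2 value of
#' each kit's channels is subtracted from that kit's channels, so each
#' protein's mean across a kit is 0. Kits are then ready to be combined for
#' statistics. Invariant to per-kit global rescaling of the raw intensities.
#'
#' @param matrix protein x channel matrix, all intensities > 0
#'   (impute first).
#' @param design a [plex_design] covering every column of `matrix`.
#' @return centered log2 matrix (class `normalized_matrix`), design attached.
#' @export
log2_center <- function(matrix, design) {
  stopifnot(inherits(design, "plex_design"))
  if (any(matrix <= 0, na.rm = TRUE) || anyNA(matrix)) {
    stop("non-positive or missing intensities: impute before log2 centering")
  }
  if (!all(colnames(matrix) %in% design$channel)) {
    stop("design does not cover all matrix channels")
  }
  lg <- log2(matrix)
  kits <- design$kit[match(colnames(matrix), design$channel)]
  for (k in unique(kits)) {
    cols <- which(kits == k)
    lg[, cols] <- lg[, cols] - rowMeans(lg[, cols, drop = FALSE])
  }
  structure(lg, design = design, class = c("normalized_matrix", class(lg)))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p p-values.
#' @return q-values (monotone step-up adjustment).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Differential protein expression
#'
#' Per-protein equal-variance (pooled) two-sample t-test between two groups of
#' channels, with Benjamini-Hochberg FDR adjustment over the tested set.
#' Significance cutoffs are parameters, not constants.
#'
#' @param norm centered log2 matrix ([log2_center()]).
#' @param groups named character vector: channel -> group label; exactly two
#'   distinct groups, each with >= 2 channels.
#' @param q_cutoff flag proteins with q below this (default 0.1).
#' @return data.frame: `protein`, `mean_<g1>`, `mean_<g2>`, `log2fc`
#'   (group2 - group1), `t`, `p`, `q`, `significant`.
#' @export
differential_expression <- function(norm, groups, q_cutoff = 0.1) {
  groups <- groups[names(groups) %in% colnames(norm)]
  gl <- unique(groups)
  if (length(gl) != 2L) stop("need exactly two groups")
  c1 <- names(groups)[groups == gl[1]]
  c2 <- names(groups)[groups == gl[2]]
  if (length(c1) < 2L || length(c2) < 2L) stop("each group needs >= 2 channels")
  x1 <- norm[, c1, drop = FALSE]; x2 <- norm[, c2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se == 0, 0, (m2 - m1) / se)
  df <- n1 + n2 - 2
  p <- ifelse(se == 0, 1, 2 * pt(abs(tt), df, lower.tail = FALSE))
  q <- bh_adjust(p)
  out <- data.frame(protein = rownames(norm), m1, m2,
                    log2fc = m2 - m1, t = tt, p = p, q = q,
                    significant = q < q_cutoff, row.names = NULL)
  names(out)[2:3] <- paste0("mean_", make.names(gl))
  out
}

#' Restrict a matrix to annotated (e.g. mitochondrial) proteins
#'
#' @param matrix protein x channel matrix with accession rownames.
#' @param accessions non-empty character vector of annotated accessions.
#' @return subset matrix; the retained fraction is in attribute
#'   `subset_fraction`. Zero overlap yields a warning and an empty matrix.
#' @export
annotation_subset <- function(matrix, accessions) {
  if (!length(accessions)) stop("annotation list is empty")
  keep <- rownames(matrix) %in% accessions
  if (!any(keep)) warning("no matrix rows match the annotation list")
  out <- matrix[keep, , drop = FALSE]
  attr(out, "subset_fraction") <- mean(keep)
  out
}

#' Bridge-channel QC correlation across kits
#'
#' Pearson correlation of the bridge sample's centered profiles between kit
#' pairs. QC only: no bridge-ratio rescaling is applied by default.
#'
#' @param norm centered log2 matrix with the design attached.
#' @return data.frame of kit pairs and correlations (empty if no bridge).
#' @export
bridge_qc <- function(norm) {
  design <- attr(norm, "design")
  br <- design[design$is_bridge, , drop = FALSE]
  if (nrow(br) < 2L) return(data.frame(kit1 = character(0), kit2 = character(0),
                                       cor = numeric(0)))
  combs <- utils::combn(seq_len(nrow(br)), 2L)
  out <- apply(combs, 2L, function(ij) {
    a <- norm[, br$channel[ij[1]]]; b <- norm[, br$channel[ij[2]]]
    data.frame(kit1 = br$kit[ij[1]], kit2 = br$kit[ij[2]],
               cor = stats::cor(a, b))
  })
  do.call(rbind, out)
}

#' Read the proteomics TSV dialects
#'
#' PSM tables: `protein,peptide,psm_id,coiso,sn,<channel columns>`; design:
#' `channel,kit,sample,group,is_bridge`; annotation: one accession per line.
#'
#' @param path file path.
#' @param channels channel columns (default: everything after `sn`).
#' @return see the corresponding constructor.
#' @export
read_psm_tsv <- function(path, channels = NULL) {
  d <- read.delim(path, check.names = FALSE)
  if (is.null(channels)) {
    i <- match("sn", names(d))
    channels <- names(d)[(i + 1L):ncol(d)]
  }
  psm_table(d, channels)
}

#' @rdname read_psm_tsv
#' @export
read_design_tsv <- function(path) {
  d <- read.delim(path)
  plex_design(as.character(d$channel), d$kit, d$sample,
              group = if ("group" %in% names(d)) d$group else NA_character_,
              is_bridge = if ("is_bridge" %in% names(d)) as.logical(d$is_bridge) else FALSE)
}

#' @importFrom utils read.delim
#' @rdname read_psm_tsv
#' @export
read_annotation <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
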