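#' Chimeric dual-species count matrix
#'
#' Container for genes x samples expected-count matrices in which every gene
#' identifier carries a species tag prefix (e.g. \code{hg19_SOX2},
#' \code{mm10_Sox2}), as produced by quantification against a joint
#' two-species transcriptome reference. Expected counts are kept as reals
#' (RSEM-style); they are never rounded to integers.
#'
#' @param counts Numeric matrix, genes in rows (rownames are tagged gene ids),
#'   samples in columns.
#' @param samples Data frame with columns \code{sample_id}, \code{mixture},
#'   \code{day}, \code{replicate}; one row per column of \code{counts}.
#' @param species_tags Character vector of recognized species tags.
#' @param sep Separator between tag and gene symbol (fixed convention: "_").
#'
#' @return An object of class \code{chimeric_matrix}: a list with elements
#'   \code{counts}, \code{samples}, \code{species_tags}, \code{sep}.
#' @export
chimeric_matrix <- function(counts, samples, species_tags = c("hg19", "mm10"),
                            sep = "_") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (!all(is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "mixture", "day", "replicate")
  if (!all(req %in% names(samples)))
    stop("samples must have columns: ", paste(req, collapse = ", "))
  samples$day <- as.numeric(samples$day)
  if (any(samples$day < 0)) stop("day must be non-negative")
  if (nrow(samples) != ncol(counts))
    stop("samples rows must match counts columns")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), as.character(samples$sample_id)))
    stop("colnames(counts) must equal samples$sample_id (in order)")
  key <- paste(samples$mixture, samples$day, samples$replicate)
  if (anyDuplicated(key))
    stop("(mixture, day, replicate) must be unique across samples")
  sp <- species_of(rownames(counts), species_tags, sep)
  bad <- rownames(counts)[is.na(sp)]
  if (length(bad))
    stop("gene ids without a recognized species prefix: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  structure(list(counts = counts, samples = samples,
                 species_tags = species_tags, sep = sep),
            class = "chimeric_matrix")
}

# tag of each gene id, NA when no recognized prefix matches
species_of <- function(gene_ids, species_tags, sep = "_") {
  out <- rep(NA_character_, length(gene_ids))
  for (tag in species_tags) {
    pre <- paste0(tag, sep)
    hit <- startsWith(gene_ids, pre) & nchar(gene_ids) > nchar(pre)
    out[hit & is.na(out)] <- tag
  }
  out
}

strip_tag <- function(gene_ids, tag, sep = "_") {
  substring(gene_ids, nchar(tag) + nchar(sep) + 1L)
}

#' @export
print.chimeric_matrix <- function(x, ...) {
  sp <- species_of(rownames(x$counts), x$species_tags, x$sep)
  cat("chimeric_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  tab <- table(sp)
  cat("  species:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  cat("  mixtures:", paste(unique(x$samples$mixture), collapse = ", "), "\n")
  cat("  days:", min(x$samples$day), "-", max(x$samples$day), "\n")
  invisible(x)
}

#' Single-species count matrix
#'
#' Genes x samples expected counts for one species, tags stripped from the
#' gene ids.
#'
#' @param counts Numeric matrix with plain gene symbols as rownames.
#' @param species Species tag the genes belong to.
#' @param samples Sample metadata data frame (see [chimeric_matrix()]).
#' @return An object of class \code{species_matrix}.
#' @export
species_matrix <- function(counts, species, samples) {
  structure(list(counts = as.matrix(counts), species = species,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "species_matrix")
}

#' @export
print.species_matrix <- function(x, ...) {
  cat("species_matrix [", x$species, "]: ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Read a species-tagged expected-count matrix
#'
#' Reads a genes x samples matrix from TSV (first column \code{gene_id},
#' remaining columns one per sample) or MatrixMarket format (\code{.mtx} file
#' plus \code{<stem>_genes.txt} and \code{<stem>_samples.txt} sidecars), and
#' attaches per-sample metadata.
#'
#' @param path Path to the TSV or .mtx file.
#' @param meta Sample metadata: a CSV path or a data frame with columns
#'   \code{sample_id}, \code{mixture}, \code{day}, \code{replicate}.
#' @param format "tsv" or "mtx"; guessed from the file extension by default.
#' @inheritParams chimeric_matrix
#' @return A [chimeric_matrix()].
#' @export
read_counts <- function(path, meta, format = c("auto", "tsv", "mtx"),
                        species_tags = c("hg19", "mm10"), sep = "_") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    tab <- tryCatch(
      utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
    if (ncol(tab) < 2) stop("parse error in ", path, ": need gene_id + samples")
    counts <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(counts)) {
      bad <- which(!apply(tab[, -1, drop = FALSE], 1, function(r)
        all(!is.na(suppressWarnings(as.numeric(r))))))[1]
      stop("parse error in ", path, ": non-numeric counts at data line ", bad)
    }
    rownames(counts) <- as.character(tab[[1]])
  } else {
    stem <- sub("\\.mtx$", "", path)
    counts <- as.matrix(Matrix::readMM(path))
    rownames(counts) <- readLines(paste0(stem, "_genes.txt"))
    colnames(counts) <- readLines(paste0(stem, "_samples.txt"))
  }
  if (is.character(meta) && length(meta) == 1)
    meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  chimeric_matrix(counts, meta, species_tags = species_tags, sep = sep)
}

#' Write a chimeric or species count matrix
#'
#' TSV writer with fixed decimal formatting (17 significant digits) so that a
#' write/read round trip reproduces values bit-exactly. A sample metadata CSV
#' is written alongside when \code{meta_path} is given.
#'
#' @param x A [chimeric_matrix()] or [species_matrix()].
#' @param path Output TSV path.
#' @param meta_path Optional path for the sample metadata CSV.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(x, path, meta_path = NULL) {
  counts <- x$counts
  header <- paste(c("gene_id", colnames(counts)), collapse = "\t")
  body <- vapply(seq_len(nrow(counts)), function(i)
    paste(c(rownames(counts)[i], sprintf("%.17g", counts[i, ])),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  if (!is.null(meta_path))
    utils::write.csv(x$samples, meta_path, row.names = FALSE)
  invisible(path)
}

#' Split a chimeric matrix by species
#'
#' Separates the human and mouse (or any tagged) subsets of expected counts
#' into per-species matrices with tags stripped. Mitochondrial genes, which
#' have inconsistent abundance across samples, are optionally removed by
#' symbol prefix before any downstream analysis or normalization.
#'
#' @param m A [chimeric_matrix()].
#' @param drop_mito Remove mitochondrial genes?
#' @param mito_pattern Regex on the stripped gene symbol identifying
#'   mitochondrial genes (default: symbols beginning \code{MT-} / \code{mt-}).
#' @param mito_genes Optional explicit symbol list overriding the pattern.
#' @return Named list of [species_matrix()], one per species tag.
#' @export
split_by_species <- function(m, drop_mito = TRUE, mito_pattern = "^[Mm][Tt]-",
                             mito_genes = NULL) {
  stopifnot(inherits(m, "chimeric_matrix"))
  sp <- species_of(rownames(m$counts), m$species_tags, m$sep)
  out <- list()
  for (tag in m$species_tags) {
    idx <- which(sp == tag)
    if (!length(idx)) {
      warning("no genes for species ", tag)
      cm <- m$counts[integer(0), , drop = FALSE]
      out[[tag]] <- species_matrix(cm, tag, m$samples)
      next
    }
    cm <- m$counts[idx, , drop = FALSE]
    rownames(cm) <- strip_tag(rownames(cm), tag, m$sep)
    if (drop_mito) {
      mito <- if (is.null(mito_genes)) grepl(mito_pattern, rownames(cm))
              else rownames(cm) %in% mito_genes
      cm <- cm[!mito, , drop = FALSE]
    }
    out[[tag]] <- species_matrix(cm, tag, m$samples)
  }
  out
}

#' Per-sample cross-species misalignment rate
#'
#' For pure-species samples, transcripts assigned to the other species'
#' portion of the joint transcriptome represent alignment errors. The rate is
#' the fraction of a sample's expected counts on genes \emph{not} tagged with
#' the expected species.
#'
#' @param m A [chimeric_matrix()].
#' @param expected_species Tag of the species the samples should contain.
#' @return Data frame: \code{sample_id}, \code{rate} (NA for zero-depth
#'   samples), \code{depth} (total expected counts), \code{flagged} (TRUE when
#'   the rate is undefined).
#' @export
misalignment_rate <- function(m, expected_species) {
  stopifnot(inherits(m, "chimeric_matrix"))
  if (!expected_species %in% m$species_tags)
    stop("unknown species tag: ", expected_species)
  sp <- species_of(rownames(m$counts), m$species_tags, m$sep)
  off <- colSums(m$counts[sp != expected_species, , drop = FALSE])
  depth <- colSums(m$counts)
  rate <- ifelse(depth > 0, off / depth, NA_real_)
  data.frame(sample_id = m$samples$sample_id, rate = rate, depth = depth,
             flagged = depth == 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Actively expressed genes
#'
#' Genes whose within-gene 0.8 quantile of expected counts across samples
#' meets a threshold (default 20). Quantiles use linear interpolation between
#' order statistics (R type 7), the convention used throughout the package.
#'
#' @param m A [species_matrix()] (or any object with a \code{counts} matrix).
#' @param quantile Quantile level.
#' @param threshold Minimum expected counts at that quantile (inclusive).
#' @return Character vector of gene symbols.
#' @export
active_genes <- function(m, quantile = 0.8, threshold = 20) {
  counts <- if (is.list(m)) m$counts else as.matrix(m)
  if (ncol(counts) < 1) stop("need at least one sample")
  q <- apply(counts, 1, stats::quantile, probs = quantile, type = 7,
             names = FALSE)
  rownames(counts)[q >= threshold]
}
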