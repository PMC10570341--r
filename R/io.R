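# Domain containers and TSV/Newick readers and writers.
#
# All tables are UTF-8 TSV with '.' decimal; trees are Newick. Readers
# validate invariants and refuse to coerce silently.

SIZE_FRACTIONS <- c("Pico", "Piconano", "Nano", "Micro", "Macro", "Broad")
BIOMES <- c("Polar", "Coastal", "Trades", "Westerlies")
DEPTH_LAYERS <- c("SRF", "DCM")

#' Construct an RPKM abundance matrix
#'
#' Container for non-negative RPKM values of entities (genomes or gene
#' families) across samples, with a parallel logical detection matrix.
#' A cell with `detected = FALSE` is treated as zero signal everywhere
#' downstream. When no detection matrix is supplied, a cell counts as
#' detected iff its RPKM is positive (the genome-coverage detection rule
#' is applied upstream of this package; the flag is consumed, not
#' computed).
#'
#' @param rpkm Numeric matrix, entities x samples, with dimnames.
#' @param detected Optional logical matrix of the same shape.
#' @return An object of class `rpkm_matrix` with elements `rpkm` and
#'   `detected`.
#' @export
rpkm_matrix <- function(rpkm, detected = NULL) {
  rpkm <- as.matrix(rpkm)
  if (nrow(rpkm) == 0) stop("no entities")
  if (is.null(rownames(rpkm)) || is.null(colnames(rpkm)))
    stop("rpkm matrix needs entity and sample dimnames")
  if (anyDuplicated(rownames(rpkm))) stop("duplicate entity ids")
  if (anyDuplicated(colnames(rpkm))) stop("duplicate sample ids")
  bad <- which(rpkm < 0 | is.na(rpkm), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or missing RPKM at entity '%s', sample '%s'",
                 rownames(rpkm)[bad[1, 1]], colnames(rpkm)[bad[1, 2]]))
  }
  if (is.null(detected)) {
    detected <- rpkm > 0
  } else {
    detected <- as.matrix(detected)
    stopifnot(identical(dim(detected), dim(rpkm)))
    mode(detected) <- "logical"
    if (anyNA(detected)) stop("detection flags must be TRUE/FALSE")
  }
  # undetected cells carry no signal
  rpkm[!detected] <- 0
  structure(list(rpkm = rpkm, detected = detected), class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat(sprintf("<rpkm_matrix> %d entities x %d samples, %.1f%% cells detected\n",
              nrow(x$rpkm), ncol(x$rpkm), 100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.rpkm_matrix <- function(x) dim(x$rpkm)

entity_ids <- function(x) rownames(x$rpkm)
sample_ids <- function(x) colnames(x$rpkm)

#' Read an abundance matrix from TSV
#'
#' Expects a header row of sample ids and a first column of entity ids.
#' Missing cells become 0 with `detected = FALSE`. An optional companion
#' TSV of 0/1 flags (same layout) supplies detection explicitly.
#'
#' @param path TSV file path.
#' @param detected_path Optional path to a 0/1 detection TSV.
#' @return An [rpkm_matrix()].
#' @export
read_abundance <- function(path, detected_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("no entities in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate entity ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  rownames(m) <- ids
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative RPKM at entity '%s', sample '%s' in %s",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  }
  m[is.na(m)] <- 0
  det <- NULL
  if (!is.null(detected_path)) {
    dd <- utils::read.delim(detected_path, check.names = FALSE)
    dm <- as.matrix(dd[, -1, drop = FALSE]) > 0
    rownames(dm) <- as.character(dd[[1]])
    det <- dm[ids, colnames(m), drop = FALSE]
  }
  rpkm_matrix(m, det)
}

#' Write an abundance matrix to TSV
#' @param x An [rpkm_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  df <- data.frame(entity_id = rownames(x$rpkm), x$rpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate (and normalise) a sample metadata table
#'
#' Checks the closed vocabularies (size fraction, biome, depth layer),
#' latitude range and sample-id uniqueness. Temperature may be missing.
#'
#' @param df Data frame with columns `sample_id`, `station_id`,
#'   `depth_layer`, `size_fraction`, `biome`, `latitude`, `temperature`.
#' @return The validated data frame.
#' @export
validate_samples <- function(df) {
  need <- c("sample_id", "station_id", "depth_layer", "size_fraction",
            "biome", "latitude", "temperature")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (any(!df$depth_layer %in% DEPTH_LAYERS))
    stop("depth_layer outside {", paste(DEPTH_LAYERS, collapse = ","), "}")
  if (any(!df$size_fraction %in% SIZE_FRACTIONS))
    stop("size_fraction outside the closed vocabulary")
  if (any(!df$biome %in% BIOMES))
    stop("biome outside the closed vocabulary")
  if (any(is.na(df$latitude)) || any(abs(df$latitude) > 90))
    stop("latitude must be within [-90, 90]")
  df
}

#' Read sample metadata from TSV
#' @param path TSV path.
#' @return Validated sample data frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_samples(df)
}

#' Read a gene annotation table (gene -> genome, KO, GCC)
#'
#' @param path TSV with columns `gene_id`, `genome_id` and optional
#'   `ko_id`, `gcc_id` (empty string or NA = unannotated).
#' @return Data frame with those columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "genome_id") %in% names(df)))
    stop("annotation table needs gene_id and genome_id columns")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id")
  for (col in c("ko_id", "gcc_id")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  df
}

#' Read a pathway -> KO membership map
#' @param path TSV in long format: `pathway_id`, `name`, `category`, `ko_id`.
#' @return Data frame with one row per (pathway, KO) pair.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "name", "category", "ko_id")
  if (!all(need %in% names(df))) stop("pathway map needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(table(df$pathway_id) == 0)) stop("empty pathway member set")
  df
}

#' Read a virus-eukaryote edge list
#' @param path TSV with `virus_id`, `eukaryote_id`, `weight`,
#'   `size_fraction`, optional `p_value`.
#' @return Validated data frame.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("virus_id", "eukaryote_id", "weight", "size_fraction")
  if (!all(need %in% names(df))) stop("edge list needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(abs(df$weight) > 1)) stop("edge weight outside [-1, 1]")
  df
}

#' Read a virus-eukaryote protein-similarity table
#' @param path TSV with `virus_id`, `eukaryote_id`, `max_protein_identity`.
#' @return Validated data frame (identities in percent).
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("virus_id", "eukaryote_id", "max_protein_identity")
  if (!all(need %in% names(df))) stop("similarity table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(df$max_protein_identity < 0 | df$max_protein_identity > 100))
    stop("protein identity outside [0, 100]")
  df
}

# Deterministic preorder naming of unlabeled internal nodes ("N<k>").
name_internal_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  if (is.null(tree$node.label)) tree$node.label <- rep("", n_node)
  tree$node.label[is.na(tree$node.label)] <- ""
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  preorder <- unique(c(n_tip + 1L, ord[, 2]))
  preorder <- preorder[preorder > n_tip]
  k <- 0L
  for (nd in preorder) {
    k <- k + 1L
    i <- nd - n_tip
    if (tree$node.label[i] == "") tree$node.label[i] <- sprintf("N%d", k)
  }
  if (anyDuplicated(tree$node.label)) stop("duplicate internal node labels")
  tree
}

#' Read a rooted, branch-lengthed Newick tree
#'
#' Unlabeled internal nodes are auto-named deterministically by preorder
#' index (`N1` = root, ...), so per-node outputs are stable across runs.
#'
#' @param path Newick file path.
#' @return An `ape` `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted (trifurcating root); root it first")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  name_internal_nodes(tree)
}

#' Write a tree to Newick
#' @param tree `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write named result tables and a JSON manifest
#'
#' Writes one TSV per named data frame plus `manifest.json` recording the
#' file name, row count and MD5 checksum of each. Bit-stable given fixed
#' inputs and seed.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data frame, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  rows <- lapply(names(tables), function(nm) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(file = basename(f), n_rows = nrow(df),
               md5 = unname(tools::md5sum(f)), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
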