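# ---- progressive multiple alignment -------------------------------------

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- get("BLOSUM62", envir = e)
    }
    cache
  }
})

# residue frequency profile of an alignment block (gaps carry no mass)
aln_profile <- function(mat, alpha) {
  P <- matrix(0, length(alpha), ncol(mat), dimnames = list(alpha, NULL))
  for (a in alpha) P[a, ] <- colMeans(mat == a)
  P
}

# merge two alignment blocks by global profile-profile alignment
merge_blocks <- function(m1, m2, B, alpha, gap_open, gap_ext) {
  S <- crossprod(aln_profile(m1, alpha), B[alpha, alpha]) %*%
    aln_profile(m2, alpha)
  path <- profile_nw_path(S, gap_open, gap_ext)
  L <- length(path)
  out <- matrix("-", nrow(m1) + nrow(m2), L)
  rownames(out) <- c(rownames(m1), rownames(m2))
  i1 <- which(path %in% c(1L, 2L))
  i2 <- which(path %in% c(1L, 3L))
  out[seq_len(nrow(m1)), i1] <- m1
  out[nrow(m1) + seq_len(nrow(m2)), i2] <- m2
  out
}

#' Progressive multiple protein alignment for one orthogroup
#'
#' Aligns the member proteins progressively: a k-mer distance matrix feeds
#' a UPGMA guide tree, whose merge order drives global profile-profile
#' alignments under BLOSUM62 with affine gaps (a gap of length L costs
#' `gap_open + L * gap_ext`). All input residues are preserved; row order
#' follows the input.
#'
#' @param proteins named character vector of >= 2 protein sequences.
#' @param gap_open,gap_ext affine gap penalties (defaults 11 and 1).
#' @return character matrix of single characters, rows named as the input.
#' @export
align_og <- function(proteins, gap_open = 11, gap_ext = 1) {
  if (length(proteins) < 2L) stop("need at least 2 sequences to align")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("s", seq_along(proteins))
  B <- blosum62()
  chars <- strsplit(proteins, "")
  alpha <- intersect(rownames(B), unique(unlist(chars, use.names = FALSE)))
  blocks <- lapply(seq_along(proteins), function(i) {
    m <- matrix(chars[[i]], nrow = 1L)
    rownames(m) <- names(proteins)[i]
    m
  })
  if (length(proteins) == 2L) {
    res <- merge_blocks(blocks[[1L]], blocks[[2L]], B, alpha,
                        gap_open, gap_ext)
    return(res[names(proteins), , drop = FALSE])
  }
  # guide tree from shared 3-mer distance
  k <- 3L
  kms <- lapply(proteins, function(s) {
    l <- nchar(s)
    if (l < k) return(character())
    unique(substring(s, 1:(l - k + 1L), k:l))
  })
  n <- length(proteins)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    denom <- max(1L, min(length(kms[[i]]), length(kms[[j]])))
    D[i, j] <- D[j, i] <- 1 - length(intersect(kms[[i]], kms[[j]])) / denom
  }
  hc <- hclust(stats::as.dist(D), method = "average")
  merged <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(x) if (x < 0L) blocks[[-x]] else merged[[x]]
    merged[[s]] <- merge_blocks(pick(hc$merge[s, 1L]),
                                pick(hc$merge[s, 2L]),
                                B, alpha, gap_open, gap_ext)
  }
  res <- merged[[n - 1L]]
  res[names(proteins), , drop = FALSE]
}

# ---- codon back-translation ---------------------------------------------

#' Back-translate a protein alignment into a codon alignment
#'
#' Expands each residue column into its source codon; residue gaps become
#' `---`. A trailing stop codon on a CDS is excluded. Any disagreement
#' between a CDS translation and its protein row is an error naming the
#' gene and the first mismatched residue.
#'
#' @param msa protein alignment: character matrix (rows named by gene) or
#'   named character vector of aligned strings.
#' @param cds named character vector of coding sequences.
#' @return a [codon_alignment()].
#' @export
protein_to_codon <- function(msa, cds) {
  m <- as_aln_matrix(msa)
  if (is.null(rownames(m))) stop("protein alignment rows must be named")
  gc <- Biostrings::GENETIC_CODE
  nuc <- matrix("-", nrow(m), 3L * ncol(m), dimnames =
                  list(rownames(m), NULL))
  for (g in rownames(m)) {
    s <- cds[[g]]
    if (is.null(s) || is.na(s)) stop("no CDS for gene ", g)
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (length(codons) && gc[codons[length(codons)]] == "*")
      codons <- codons[-length(codons)]
    res <- m[g, ] != "-"
    if (sum(res) != length(codons))
      stop("gene ", g, ": CDS has ", length(codons),
           " codons but protein row has ", sum(res), " residues")
    aa <- unname(gc[codons])
    mism <- which(aa != m[g, res])
    if (length(mism))
      stop("gene ", g, ": CDS disagrees with protein at residue ", mism[1L])
    cols <- which(res)
    nuc[g, c(rbind(3L * cols - 2L, 3L * cols - 1L, 3L * cols))] <-
      unlist(strsplit(codons, ""), use.names = FALSE)
  }
  codon_alignment(nuc)
}

# ---- outlier detection --------------------------------------------------

#' Flag outlier sequences in a protein alignment
#'
#' Computes each row's mean pairwise distance (proportion of mismatching
#' columns, double-gap columns excluded per pair), bootstraps the column
#' set to estimate the spread of each row's mean distance, and flags rows
#' whose observed mean exceeds the across-row trimmed mean by more than
#' `z_max` bootstrap standard deviations. Catches non-homologous,
#' mistranslated and low-similarity members before tree building.
#'
#' @param msa protein alignment (matrix or named strings).
#' @param bootstrap_reps bootstrap replicates over columns (default 100).
#' @param seed optional seed for the bootstrap.
#' @param z_max flagging threshold (default 3).
#' @return character vector of outlier gene ids (empty for < 5 rows).
#' @export
detect_outliers <- function(msa, bootstrap_reps = 100L, seed = NULL,
                            z_max = 3) {
  m <- as_aln_matrix(msa)
  n <- nrow(m)
  if (n < 5L) return(character())
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(m)
  pairs <- combn(n, 2L)
  np <- ncol(pairs)
  mism <- matrix(FALSE, np, L)
  valid <- matrix(TRUE, np, L)
  for (p in seq_len(np)) {
    a <- m[pairs[1L, p], ]; b <- m[pairs[2L, p], ]
    both_gap <- a == "-" & b == "-"
    mism[p, ] <- a != b & !both_gap
    valid[p, ] <- !both_gap
  }
  d_pair <- rowSums(mism) / pmax(1L, rowSums(valid))
  inc <- matrix(0, n, np)  # row-to-pair incidence
  inc[cbind(pairs[1L, ], seq_len(np))] <- 1
  inc[cbind(pairs[2L, ], seq_len(np))] <- 1
  d_row <- as.vector(inc %*% d_pair) / (n - 1L)
  boot_sd <- {
    reps <- matrix(0, n, bootstrap_reps)
    for (b in seq_len(bootstrap_reps)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      db <- (mism %*% w) / pmax(1, valid %*% w)
      reps[, b] <- as.vector(inc %*% db) / (n - 1L)
    }
    apply(reps, 1L, sd)
  }
  center <- mean(d_row, trim = 0.2)
  z <- ifelse(boot_sd > 1e-12, (d_row - center) / boot_sd, 0)
  rownames(m)[z > z_max]
}

# ---- tree building ------------------------------------------------------

codon_dist <- function(m) {
  dn <- ape::as.DNAbin(tolower(m))
  d <- ape::dist.dna(dn, model = "raw", pairwise.deletion = TRUE)
  d[is.na(d) | is.nan(d)] <- max(d, 0, na.rm = TRUE)
  d
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Builds a neighbor-joining tree from pairwise p-distances (gaps deleted
#' pairwise) on a codon alignment, clamps negative branch lengths to zero,
#' and attaches percent support from codon-column bootstrap replicates as
#' node labels.
#'
#' @param aln a [codon_alignment()] or nucleotide character matrix with
#'   named rows.
#' @param bootstrap_reps bootstrap replicates (default 100); 0 skips
#'   support estimation.
#' @param seed optional seed for the bootstrap.
#' @return an [ape::phylo] tree; internal `node.label` carry percent
#'   support (root label empty). For 2 rows, a degenerate two-leaf tree
#'   without supports.
#' @export
build_tree <- function(aln, bootstrap_reps = 100L, seed = NULL) {
  m <- as_aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  if (!is.null(seed)) set.seed(seed)
  if (n == 2L) {
    d <- as.numeric(codon_dist(m))
    tr <- structure(list(
      edge = matrix(c(3L, 3L, 1L, 2L), 2L),
      edge.length = c(d / 2, d / 2),
      tip.label = rownames(m), Nnode = 1L), class = "phylo")
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(codon_dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (bootstrap_reps > 0L && n > 3L) {
    ncodon <- ncol(m) %/% 3L
    boots <- vector("list", bootstrap_reps)
    for (b in seq_len(bootstrap_reps)) {
      cod <- sample.int(ncodon, ncodon, replace = TRUE)
      cols <- c(rbind(3L * cod - 2L, 3L * cod - 1L, 3L * cod))
      bt <- ape::nj(codon_dist(m[, cols, drop = FALSE]))
      boots[[b]] <- bt
    }
    cnt <- ape::prop.clades(tr, boots, rooted = FALSE)
    cnt[is.na(cnt)] <- 0L
    tr$node.label <- as.character(round(100 * cnt / bootstrap_reps))
    tr$node.label[1L] <- ""
  } else {
    tr$node.label <- rep("", tr$Nnode)
  }
  tr
}

# ---- duplication detection and the 5% rule ------------------------------

root_midpoint <- function(tree) {
  if (ape::is.rooted(tree) && ape::is.binary(tree)) return(tree)
  out <- tryCatch(phangorn::midpoint(tree), error = function(e) NULL)
  if (is.null(out) || !ape::is.rooted(out))
    out <- ape::root(tree, outgroup = tree$tip.label[1L],
                     resolve.root = TRUE)
  out
}

#' Detect duplication nodes in a gene tree
#'
#' After midpoint rooting, an internal node is a duplication node if some
#' accession occurs in more than one of its child clades. A duplication is
#' `simple` when the two occurrences are sister leaves (both children of
#' the node are tips of the same accession) and `complex` otherwise.
#'
#' @param tree an [ape::phylo] gene tree.
#' @param accession_of_gene named character vector gene id -> accession.
#' @return list with `tree` (the rooted tree used), and `duplications`
#'   (data.frame: node, type).
#' @export
detect_duplications <- function(tree, accession_of_gene) {
  tr <- root_midpoint(tree)
  ntip <- length(tr$tip.label)
  acc <- accession_of_gene[tr$tip.label]
  if (any(is.na(acc))) stop("every leaf needs an accession")
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  tipsets <- phangorn::Descendants(tr, (ntip + 1L):(ntip + tr$Nnode), "tips")
  tipset_of <- function(node)
    if (node <= ntip) node else tipsets[[node - ntip]]
  nodes <- integer(); types <- character()
  for (nd in (ntip + 1L):(ntip + tr$Nnode)) {
    ch <- kids[[as.character(nd)]]
    if (length(ch) < 2L) next
    accsets <- lapply(ch, function(c2) unique(acc[tipset_of(c2)]))
    shared <- FALSE
    for (i in seq_len(length(ch) - 1L))
      for (j in (i + 1L):length(ch))
        if (length(intersect(accsets[[i]], accsets[[j]]))) shared <- TRUE
    if (!shared) next
    simple <- length(ch) == 2L && all(ch <= ntip) &&
      acc[ch[1L]] == acc[ch[2L]]
    nodes <- c(nodes, nd)
    types <- c(types, if (simple) "simple" else "complex")
  }
  list(tree = tr,
       duplications = data.frame(node = nodes, type = types))
}

# recursive split of a rooted tree at duplication nodes: returns a list of
# leaf-label sets
split_at_duplications <- function(tree, dup_nodes) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(node) {
    if (node <= ntip) return(list(tree$tip.label[node]))
    if (node %in% dup_nodes) {
      unlist(lapply(kids[[as.character(node)]], rec), recursive = FALSE)
    } else {
      tips <- phangorn::Descendants(tree, node, "tips")[[1L]]
      list(tree$tip.label[tips])
    }
  }
  rec(ntip + 1L)
}

#' Refine one orthogroup by the 5% paralog rule
#'
#' Let f be the fraction of occupied accessions showing within-orthogroup
#' duplicates. If f is at most `paralog_accession_fraction`, all paralogs
#' are removed, keeping per duplicated accession the member with the
#' smallest root-to-leaf path (the most conserved copy). Otherwise the
#' rooted tree is split at its duplication nodes; every resulting leaf set
#' with >= 2 members becomes a new orthogroup (`<og_id>.1`, ...) and the
#' remainder become singletons.
#'
#' @param og_id orthogroup id.
#' @param members character vector of member gene ids.
#' @param tree the orthogroup's gene tree ([build_tree()]).
#' @param accession_of_gene named character vector gene id -> accession.
#' @param paralog_accession_fraction the 5% rule threshold (default 0.05).
#' @return list with `ogs` (named list of member vectors) and `log`
#'   (data.frame: gene_id, status; status one of `kept`,
#'   `pruned_paralog`, `split_to:<id>`, `singleton`).
#' @export
refine_og <- function(og_id, members, tree, accession_of_gene,
                      paralog_accession_fraction = 0.05) {
  acc <- accession_of_gene[members]
  occupied <- unique(acc)
  tb <- table(acc)
  dup_accs <- names(tb)[tb > 1L]
  if (!length(dup_accs)) {
    return(list(ogs = setNames(list(sort(members)), og_id),
                log = data.frame(gene_id = members, status = "kept")))
  }
  f <- length(dup_accs) / length(occupied)
  dd <- detect_duplications(tree, accession_of_gene)
  tr <- dd$tree
  if (f <= paralog_accession_fraction) {
    depth <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    names(depth) <- tr$tip.label
    status <- setNames(rep("kept", length(members)), members)
    for (a in dup_accs) {
      gs <- members[acc == a]
      keep <- gs[order(depth[gs], gs)][1L]
      status[setdiff(gs, keep)] <- "pruned_paralog"
    }
    kept <- names(status)[status == "kept"]
    return(list(ogs = setNames(list(sort(kept)), og_id),
                log = data.frame(gene_id = names(status),
                                 status = unname(status))))
  }
  parts <- split_at_duplications(tr, dd$duplications$node)
  parts <- parts[order(-lengths(parts),
                       vapply(parts, function(x) sort(x)[1L], ""))]
  ogs <- list(); status <- setNames(rep("singleton", length(members)),
                                    members)
  k <- 0L
  for (p in parts) {
    if (length(p) < 2L) next
    k <- k + 1L
    nid <- paste0(og_id, ".", k)
    ogs[[nid]] <- sort(p)
    status[p] <- paste0("split_to:", nid)
  }
  list(ogs = ogs, log = data.frame(gene_id = names(status),
                                   status = unname(status)))
}

#' Orthogroup prevalence type from size
#'
#' Fewer than 13 members is `cloud`, 13 to 51 is `shell`, more than 51 is
#' `core`.
#'
#' @param og_size integer vector of orthogroup sizes (>= 2).
#' @return character vector of types.
#' @export
classify_og_type <- function(og_size) {
  if (any(og_size < 2L)) stop("orthogroups have at least 2 members")
  ifelse(og_size < 13L, "cloud", ifelse(og_size <= 51L, "shell", "core"))
}

# ---- physical organization ----------------------------------------------

#' Detect physical NLR clusters
#'
#' Single-linkage chaining per contig: genes whose start-to-start distance
#' to a chain neighbor is within the window share a cluster; only chains
#' of >= 2 genes count as clusters.
#'
#' @param genes data.frame with columns `gene_id`, `accession`, `contig`,
#'   `start`.
#' @param window chaining window in bases (default 200000).
#' @return data.frame: `gene_id`, `clustered` (logical), `cluster_id`
#'   (NA when unclustered).
#' @export
detect_physical_clusters <- function(genes, window = 200000) {
  out <- lapply(split(genes, paste(genes$accession, genes$contig, sep = "\r")),
                function(g) {
    g <- g[order(g$start), , drop = FALSE]
    brk <- c(0L, cumsum(diff(g$start) > window))
    cid <- paste0(g$accession[1L], ":", g$contig[1L], ":", brk + 1L)
    sizes <- table(cid)
    clustered <- sizes[cid] >= 2L
    data.frame(gene_id = g$gene_id, clustered = as.vector(clustered),
               cluster_id = ifelse(clustered, cid, NA_character_))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(genes$gene_id, res$gene_id), , drop = FALSE]
}

#' Detect head-to-head (divergently transcribed) gene pairs
#'
#' Two genes are paired when they are adjacent on the same contig (no gene
#' between them), the left gene lies on the minus strand and the right
#' gene on the plus strand (divergent transcription), and their 5' ends
#' are separated by at most `max_separation` bases.
#'
#' @param genes data.frame with columns `gene_id`, `accession`, `contig`,
#'   `start`, `end`, `strand`.
#' @param max_separation maximal 5'-to-5' distance in bases (default
#'   10000).
#' @return data.frame: `accession`, `gene_left`, `gene_right`,
#'   `separation`.
#' @export
detect_pairs <- function(genes, max_separation = 10000) {
  bad <- is.na(genes$strand) | !(genes$strand %in% c("+", "-"))
  if (any(bad)) {
    warning("skipping ", sum(bad), " gene(s) with missing strand")
    genes <- genes[!bad, , drop = FALSE]
  }
  rows <- lapply(split(genes, paste(genes$accession, genes$contig,
                                    sep = "\r")), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    i <- seq_len(nrow(g) - 1L)
    sep <- g$start[i + 1L] - g$end[i]
    hit <- g$strand[i] == "-" & g$strand[i + 1L] == "+" &
      sep <= max_separation
    if (!any(hit)) return(NULL)
    data.frame(accession = g$accession[which(hit)],
               gene_left = g$gene_id[which(hit)],
               gene_right = g$gene_id[which(hit) + 1L],
               separation = sep[hit])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(), gene_left = character(),
                      gene_right = character(), separation = numeric())
  rownames(out) <- NULL
  out
}

#' Annotate a refined orthogroup with metadata votes
#'
#' Class and clustered/paired flags are majority votes over members (a
#' class tie resolves to the lexically first class with a warning); the
#' ID flag is true if any member carries an integrated domain; the mean
#' branch length is the tree's total branch length divided by the
#' orthogroup size.
#'
#' @param og_id orthogroup id.
#' @param members member gene ids.
#' @param meta data.frame with columns `gene_id`, `class`, `clustered`,
#'   `paired`, `has_id`.
#' @param tree optional gene tree for the branch-length summary.
#' @return one-row data.frame: og_id, size, og_type, class, clustered_flag,
#'   paired_flag, id_flag, mean_branch_length.
#' @export
annotate_og <- function(og_id, members, meta, tree = NULL) {
  mm <- meta[match(members, meta$gene_id), , drop = FALSE]
  cls <- table(stats::na.omit(mm$class))
  class_label <- NA_character_
  if (length(cls)) {
    top <- names(cls)[cls == max(cls)]
    if (length(top) > 1L)
      warning("class tie in ", og_id, ": ", paste(top, collapse = "/"),
              "; taking lexically first")
    class_label <- sort(top)[1L]
  }
  data.frame(
    og_id = og_id, size = length(members),
    og_type = classify_og_type(length(members)),
    class = class_label,
    clustered_flag = mean(mm$clustered, na.rm = TRUE) > 0.5,
    paired_flag = mean(mm$paired, na.rm = TRUE) > 0.5,
    id_flag = any(mm$has_id, na.rm = TRUE),
    mean_branch_length = if (!is.null(tree))
      sum(tree$edge.length) / length(members) else NA_real_)
}
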