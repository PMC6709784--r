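#' Configuration for the synthetic pan-NLRome simulator
#'
#' Bundles and validates every tunable of [simulate_pannlrome()]. The
#' defaults describe the study conditions used throughout the package's
#' tests: a 64-accession panel with a core/shell/cloud presence spectrum
#' whose type proportions echo a typical species-wide NLR complement.
#'
#' @param n_accessions number of accessions in the panel (>= 2).
#' @param og_spectrum data.frame with columns `p` (presence probability per
#'   accession, in (0, 1]) and `n` (number of orthogroups drawn at that
#'   probability).
#' @param per_og_theta scaled mutation rate per site within an orthogroup;
#'   the expected pairwise nucleotide divergence of two members.
#' @param gene_conversion_rate expected gene-conversion events per gene.
#' @param conversion_tract_mean mean conversion tract length in bases.
#' @param paralog_og_fraction fraction of orthogroups seeded with one
#'   within-accession duplicate copy.
#' @param id_gene_fraction per-gene probability of carrying an integrated
#'   domain.
#' @param pair_fraction fraction of orthogroups arranged as head-to-head
#'   (divergently transcribed) pairs.
#' @param cluster_window physical clustering window in bases.
#' @param cluster_og_fraction fraction of unpaired orthogroups placed in
#'   multi-orthogroup physical clusters.
#' @param class_probs sampling probabilities for the TNL/CNL/RNL/NL classes.
#' @param gene_length_codons integer range from which per-orthogroup protein
#'   lengths (in codons) are drawn.
#' @param seed integer random seed; the whole simulation is deterministic
#'   given the config.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_accessions = 64,
                              og_spectrum = data.frame(
                                p = c(0.95, 0.50, 0.12),
                                n = c(35, 45, 70)),
                              per_og_theta = 0.02,
                              gene_conversion_rate = 0.05,
                              conversion_tract_mean = 120,
                              paralog_og_fraction = 0.1,
                              id_gene_fraction = 0.05,
                              pair_fraction = 0.1,
                              cluster_window = 200000,
                              cluster_og_fraction = 0.4,
                              class_probs = c(TNL = 0.58, CNL = 0.22,
                                              RNL = 0.07, NL = 0.13),
                              gene_length_codons = c(80, 120),
                              seed = 1L) {
  og_spectrum <- as.data.frame(og_spectrum)
  if (!all(c("p", "n") %in% names(og_spectrum)))
    stop("og_spectrum must have columns 'p' and 'n'")
  if (any(og_spectrum$p <= 0) || any(og_spectrum$p > 1))
    stop("spectrum presence probabilities must lie in (0, 1]")
  if (any(og_spectrum$n < 1))
    stop("spectrum orthogroup counts must be positive")
  if (n_accessions < 2) stop("n_accessions must be >= 2")
  probs <- c(gene_conversion_rate >= 0, per_og_theta >= 0,
             paralog_og_fraction >= 0, paralog_og_fraction <= 1,
             id_gene_fraction >= 0, id_gene_fraction <= 1,
             pair_fraction >= 0, pair_fraction <= 1,
             cluster_og_fraction >= 0, cluster_og_fraction <= 1)
  if (!all(probs)) stop("rates must be non-negative; fractions in [0, 1]")
  structure(list(
    n_accessions = as.integer(n_accessions), og_spectrum = og_spectrum,
    per_og_theta = per_og_theta, gene_conversion_rate = gene_conversion_rate,
    conversion_tract_mean = conversion_tract_mean,
    paralog_og_fraction = paralog_og_fraction,
    id_gene_fraction = id_gene_fraction, pair_fraction = pair_fraction,
    cluster_window = cluster_window, cluster_og_fraction = cluster_og_fraction,
    class_probs = class_probs, gene_length_codons = gene_length_codons,
    seed = as.integer(seed)), class = "simulation_config")
}

# catalogue of integrated-domain labels; the labels are arbitrary tokens,
# only their non-canonical status matters downstream
ID_CATALOGUE <- c("WRKY_like", "B3_like", "TCP_like", "kinase_like",
                  "PAH_like", "DUF640_like", "PP2_like", "alliinase_like",
                  "BRX_like", "zf_like")

STOP_CODONS <- c("TAA", "TAG", "TGA")
NUCS <- c("A", "C", "G", "T")

# random stop-free coding sequence of l_codons codons, as a character vector
random_cds <- function(l_codons) {
  codons <- character(l_codons)
  pool <- apply(expand.grid(NUCS, NUCS, NUCS), 1L, paste0, collapse = "")
  pool <- setdiff(pool, STOP_CODONS)
  codons <- sample(pool, l_codons, replace = TRUE)
  unlist(strsplit(codons, ""), use.names = FALSE)
}

# Apply n_mut Jukes-Cantor point mutations to a nucleotide character vector.
# In stop-avoiding mode a mutation that would create an in-frame stop codon
# is discarded (coding sequences stay translatable end to end).
mutate_seq <- function(seq, n_mut, avoid_stops = TRUE) {
  if (n_mut == 0L) return(seq)
  pos <- sample.int(length(seq), n_mut, replace = TRUE)
  for (p in pos) {
    new <- sample(setdiff(NUCS, seq[p]), 1L)
    if (avoid_stops) {
      ci <- (p - 1L) %/% 3L
      codon <- seq[(ci * 3L + 1L):(ci * 3L + 3L)]
      codon[(p - 1L) %% 3L + 1L] <- new
      if (paste0(codon, collapse = "") %in% STOP_CODONS) next
    }
    seq[p] <- new
  }
  seq
}

# Evolve sequences down a coalescent genealogy: Poisson(theta/2 * branch
# length * L) mutations per branch under Jukes-Cantor.
evolve_on_tree <- function(tree, ancestral, theta, avoid_stops = TRUE) {
  L <- length(ancestral)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- ancestral
  ord <- rev(ape::postorder(tree))  # edges parent-first
  for (e in ord) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    n_mut <- rpois(1L, theta / 2 * tree$edge.length[e] * L)
    seqs[[child]] <- mutate_seq(seqs[[par]], n_mut, avoid_stops)
  }
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- tree$tip.label
  m
}

#' Simulate a neutral codon alignment under the standard coalescent
#'
#' Draws a Kingman coalescent genealogy (exponential waiting times, time in
#' units of 2N generations) and places Poisson mutations on its branches
#' under a Jukes-Cantor model, so that for two sequences the expected
#' pairwise difference per site equals `theta`. The returned alignment is
#' ungapped.
#'
#' @param n_sequences number of sequences (>= 2).
#' @param length alignment length in bases; must be divisible by 3.
#' @param theta scaled per-site mutation rate (4N mu).
#' @param seed integer seed; the alignment is deterministic given it.
#' @param avoid_stops logical; discard mutations that would create in-frame
#'   stop codons (default `TRUE`, so rows remain valid coding sequence).
#' @return a [codon_alignment()] with rows `seq1 ... seqn`.
#' @export
simulate_neutral_alignment <- function(n_sequences, length, theta,
                                       seed = NULL, avoid_stops = TRUE) {
  if (length %% 3L != 0L) stop("length must be divisible by 3")
  if (n_sequences < 2L) stop("need at least 2 sequences")
  if (theta < 0) stop("theta must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rcoal(n_sequences,
                     tip.label = paste0("seq", seq_len(n_sequences)))
  anc <- random_cds(length %/% 3L)
  m <- evolve_on_tree(tree, anc, theta, avoid_stops)
  codon_alignment(m[paste0("seq", seq_len(n_sequences)), , drop = FALSE])
}

#' Copy a donor tract into an acceptor sequence (gene conversion)
#'
#' Replaces the acceptor row's bases over a tract with the donor row's
#' bases; every position outside the tract is untouched.
#'
#' @param alignment a [codon_alignment()] or character matrix.
#' @param donor_index,acceptor_index row indices (or row names).
#' @param tract integer vector `c(start, end)`, 1-based inclusive alignment
#'   coordinates.
#' @return the modified alignment, same class as the input's matrix form.
#' @export
inject_gene_conversion <- function(alignment, donor_index, acceptor_index,
                                   tract) {
  m <- as_aln_matrix(alignment)
  if (is.character(donor_index)) donor_index <- match(donor_index, rownames(m))
  if (is.character(acceptor_index))
    acceptor_index <- match(acceptor_index, rownames(m))
  if (is.na(donor_index) || is.na(acceptor_index) ||
      donor_index < 1L || donor_index > nrow(m) ||
      acceptor_index < 1L || acceptor_index > nrow(m))
    stop("donor/acceptor index out of range")
  if (length(tract) != 2L || tract[1L] < 1L || tract[2L] > ncol(m) ||
      tract[1L] > tract[2L])
    stop("tract must lie within the alignment")
  idx <- tract[1L]:tract[2L]
  m[acceptor_index, idx] <- m[donor_index, idx]
  if (inherits(alignment, "codon_alignment"))
    codon_alignment(m, alignment$domains)
  else m
}

# domain interval template for one gene; returns data.frame(label, start,
# end, source) in protein coordinates, plus the truth architecture
domain_template <- function(class_label, len, id_label = NA_character_) {
  p <- function(f) max(1L, round(f * len))
  rows <- list()
  add <- function(label, s, e, source = "pfam")
    rows[[length(rows) + 1L]] <<- data.frame(label = label, start = s, end = e,
                                             source = source)
  if (class_label == "TNL") add("TIR", 1L, p(0.18))
  if (class_label == "RNL") add("RPW8", 1L, p(0.15))
  if (class_label == "CNL") {
    # CC has no Pfam track: emitted as overlapping predictor calls so the
    # two-of-three vote recovers it
    add("CC", 1L, p(0.14), source = "coils")
    add("CC", 3L, p(0.14) + 2L, source = "paircoil")
    if (runif(1L) < 0.5) add("CC", 2L, p(0.13), source = "nlrparser")
  }
  add("NB", p(0.25), p(0.50))
  lrr_end <- if (is.na(id_label)) p(0.95) else p(0.90)
  add("LRR", p(0.55), p(0.72))
  add("LRR", p(0.75), lrr_end)
  if (!is.na(id_label)) add(id_label, p(0.92), len)
  df <- do.call(rbind, rows)
  arch <- df$label[df$source %in% c("pfam", "coils")]
  ordn <- order(df$start[df$source %in% c("pfam", "coils")])
  list(domains = df, architecture = arch[ordn])
}

#' Simulate a ground-truthed synthetic pan-NLRome
#'
#' Generates a complete synthetic panel: orthogroups with a configured
#' core/shell/cloud presence spectrum, member coding sequences evolved from
#' a common ancestor on per-orthogroup coalescent genealogies, canonical
#' domain architectures with a minority of integrated domains, optional
#' within-accession paralog copies and gene conversion, and a physical
#' layout with clustered contigs and head-to-head pairs. Everything is
#' deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return an object of class `pannlrome_sim`: a list with elements
#'   `genes` (data.frame: gene_id, accession, contig, start, end, strand,
#'   flags), `proteins` and `cds` (named character vectors), `domains`
#'   (data.frame: gene_id, label, start, end, source), `truth` (list:
#'   `og_of_gene`, `architecture`, `pairs`, `clusters`), `presence`
#'   (orthogroup x accession member-count matrix) and `config`.
#' @export
simulate_pannlrome <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config")
  set.seed(config$seed)
  n_acc <- config$n_accessions
  acc_ids <- sprintf("acc%02d", seq_len(n_acc))

  # orthogroup table
  sp <- config$og_spectrum
  og_p <- rep(sp$p, sp$n)
  n_og <- length(og_p)
  og_ids <- sprintf("tOG%03d", seq_len(n_og))
  og_class <- sample(names(config$class_probs), n_og, replace = TRUE,
                     prob = config$class_probs)
  lr <- config$gene_length_codons
  og_len <- sample(lr[1L]:lr[2L], n_og, replace = TRUE)

  # head-to-head pairing: partners drawn within the same spectrum tier so
  # that co-presence is common
  partner <- rep(NA_integer_, n_og)
  n_pair_og <- 2L * floor(config$pair_fraction * n_og / 2)
  if (n_pair_og >= 2L) {
    tier <- rep(seq_len(nrow(sp)), sp$n)
    cand <- unlist(lapply(split(seq_len(n_og), tier), function(ix)
      head(ix, 2L * (length(ix) %/% 2L))), use.names = FALSE)
    cand <- head(cand, n_pair_og)
    for (i in seq(1L, length(cand), by = 2L)) {
      partner[cand[i]] <- cand[i + 1L]
      partner[cand[i + 1L]] <- cand[i]
    }
  }

  # physical grouping: each paired couple is one group; a fraction of the
  # remaining orthogroups form multi-orthogroup clusters of 2-4
  group_of <- rep(NA_integer_, n_og)
  g <- 0L
  for (i in seq_len(n_og)) {
    if (!is.na(group_of[i])) next
    g <- g + 1L
    group_of[i] <- g
    if (!is.na(partner[i])) group_of[partner[i]] <- g
  }
  free <- which(is.na(partner))
  free <- free[runif(length(free)) < config$cluster_og_fraction]
  free <- sample(free)
  while (length(free) >= 2L) {
    take <- min(sample(2:4, 1L), length(free))
    group_of[free[seq_len(take)[-1L]]] <- group_of[free[1L]]
    free <- free[-seq_len(take)]
  }

  # presence sampling and paralog seeding
  pres <- matrix(rbinom(n_og * n_acc, 1L, rep(og_p, n_acc)), n_og, n_acc,
                 dimnames = list(og_ids, acc_ids))
  paralog_og <- which(runif(n_og) < config$paralog_og_fraction)
  dup_acc <- rep(NA_integer_, n_og)
  for (i in paralog_og) {
    occ <- which(pres[i, ] > 0L)
    if (length(occ)) dup_acc[i] <- sample(occ, 1L)
  }

  genes <- list(); proteins <- character(); cds <- character()
  domains <- list(); truth_og <- character(); truth_arch <- character()
  gene_of_cell <- vector("list", n_og)  # per og: named by accession

  counter <- integer(n_acc)
  new_gene_id <- function(ai) {
    counter[ai] <<- counter[ai] + 1L
    sprintf("%s_g%04d", acc_ids[ai], counter[ai])
  }

  for (i in seq_len(n_og)) {
    occ <- which(pres[i, ] > 0L)
    if (!length(occ)) next
    m <- length(occ)
    has_dup <- !is.na(dup_acc[i])
    anc <- random_cds(og_len[i])
    if (m >= 2L) {
      tr <- ape::rcoal(m, tip.label = paste0("t", seq_len(m)))
      seqm <- evolve_on_tree(tr, anc, config$per_og_theta)
      seqm <- seqm[paste0("t", seq_len(m)), , drop = FALSE]
    } else {
      seqm <- matrix(mutate_seq(anc, rpois(1L, config$per_og_theta / 2 *
                                             length(anc))), nrow = 1L)
    }
    # gene conversion between members
    if (config$gene_conversion_rate > 0 && m >= 2L) {
      for (r in seq_len(m)) {
        nev <- rpois(1L, config$gene_conversion_rate)
        for (k in seq_len(nev)) {
          don <- sample(setdiff(seq_len(m), r), 1L)
          tl <- min(ncol(seqm),
                    max(3L, round(rexp(1L, 1 / config$conversion_tract_mean))))
          st <- sample.int(ncol(seqm) - tl + 1L, 1L)
          seqm[r, st:(st + tl - 1L)] <- seqm[don, st:(st + tl - 1L)]
        }
      }
    }
    rows <- seq_len(m)
    members <- character(m + has_dup)
    seq_list <- vector("list", m + has_dup)
    acc_of_member <- integer(m + has_dup)
    for (r in rows) {
      ai <- occ[r]
      gid <- new_gene_id(ai)
      members[r] <- gid; acc_of_member[r] <- ai
      seq_list[[r]] <- seqm[r, ]
    }
    if (has_dup) {
      ai <- dup_acc[i]
      src <- which(acc_of_member[rows] == ai)[1L]
      extra <- mutate_seq(seq_list[[src]],
                          rpois(1L, 2 * config$per_og_theta * og_len[i] * 3L))
      gid <- new_gene_id(ai)
      members[m + 1L] <- gid; acc_of_member[m + 1L] <- ai
      seq_list[[m + 1L]] <- extra
    }
    for (r in seq_along(members)) {
      gid <- members[r]
      sq <- seq_list[[r]]
      cds[gid] <- paste0(sq, collapse = "")
      proteins[gid] <- translate_cds(cds[gid])
      id_label <- if (runif(1L) < config$id_gene_fraction)
        sample(ID_CATALOGUE, 1L) else NA_character_
      tpl <- domain_template(og_class[i], og_len[i], id_label)
      dm <- tpl$domains; dm$gene_id <- gid
      domains[[length(domains) + 1L]] <- dm[, c("gene_id", "label",
                                                "start", "end", "source")]
      truth_og[gid] <- og_ids[i]
      truth_arch[gid] <- paste(tpl$architecture, collapse = ";")
    }
    gene_of_cell[[i]] <- setNames(members, acc_ids[acc_of_member])
  }

  # physical layout: per accession, one contig per group with >= 1 present
  # gene; intergenic spacing uniform in [2 kb, 50 kb]; paired orthogroups
  # adjacent, divergently transcribed, 1-8 kb apart
  gene_rows <- list()
  truth_pairs <- list()
  truth_clusters <- list()
  rare_flags <- c("truncated", "pseudogene", "mod")
  for (ai in seq_len(n_acc)) {
    acc <- acc_ids[ai]
    ctg <- 0L
    for (grp in unique(group_of)) {
      ogs_in <- which(group_of == grp)
      present <- list()
      for (i in ogs_in) {
        gm <- gene_of_cell[[i]]
        gids <- gm[names(gm) == acc]
        for (gid in gids) present[[length(present) + 1L]] <-
            list(og = i, gid = gid)
      }
      if (!length(present)) next
      ctg <- ctg + 1L
      contig <- sprintf("%s_ctg%03d", acc, ctg)
      pos <- 1000L
      is_pair_grp <- length(ogs_in) == 2L && !is.na(partner[ogs_in[1L]]) &&
        length(present) == 2L
      prev_end <- NA_integer_
      for (k in seq_along(present)) {
        gid <- present[[k]]$gid
        glen <- nchar(cds[gid])
        if (k > 1L) {
          gap <- if (is_pair_grp) round(runif(1L, 1000, 8000))
                 else round(runif(1L, 2000, 50000))
          pos <- prev_end + gap
        }
        strand <- if (is_pair_grp) c("-", "+")[k] else sample(c("+", "-"), 1L)
        flags <- character()
        if (runif(1L) < 0.02) flags <- sample(rare_flags, 1L)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gid, accession = acc, contig = contig,
          start = pos, end = pos + glen - 1L, strand = strand,
          flags = paste(flags, collapse = ","))
        prev_end <- pos + glen - 1L
      }
      if (is_pair_grp)
        truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
          accession = acc, gene_left = present[[1L]]$gid,
          gene_right = present[[2L]]$gid)
      if (length(present) >= 2L)
        truth_clusters[[length(truth_clusters) + 1L]] <-
          vapply(present, `[[`, "", "gid")
    }
  }

  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  domains <- do.call(rbind, domains)
  rownames(domains) <- NULL
  presence <- t(vapply(seq_len(n_og), function(i) {
    out <- integer(n_acc)
    gm <- gene_of_cell[[i]]
    if (length(gm)) {
      tb <- table(names(gm))
      out[match(names(tb), acc_ids)] <- as.integer(tb)
    }
    out
  }, integer(n_acc)))
  dimnames(presence) <- list(og_ids, acc_ids)

  structure(list(
    genes = genes, proteins = proteins, cds = cds, domains = domains,
    presence = presence,
    truth = list(
      og_of_gene = truth_og,
      architecture = truth_arch,
      pairs = if (length(truth_pairs)) do.call(rbind, truth_pairs) else
        data.frame(accession = character(), gene_left = character(),
                   gene_right = character()),
      clusters = truth_clusters),
    config = config), class = "pannlrome_sim")
}

#' @export
print.pannlrome_sim <- function(x, ...) {
  cat("synthetic pan-NLRome:", length(x$proteins), "genes,",
      nrow(x$presence), "truth orthogroups,",
      x$config$n_accessions, "accessions\n")
  invisible(x)
}

translate_cds <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

#' Write a simulated pan-NLRome to disk
#'
#' Emits per-accession GFF3 (gene/mRNA/CDS features, flags in `note=`),
#' protein FASTA and CDS FASTA, plus panel-wide domain and truth TSVs and
#' the configuration as a YAML key-value file.
#'
#' @param sim a `pannlrome_sim` from [simulate_pannlrome()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written file paths.
#' @export
write_pannlrome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (acc in unique(sim$genes$accession)) {
    gm <- sim$genes[sim$genes$accession == acc, , drop = FALSE]
    p <- file.path(dir, paste0(acc, ".gff3"))
    write_gff3(gm, p)
    fp <- file.path(dir, paste0(acc, ".protein.fasta"))
    write_fasta(sim$proteins[gm$gene_id], fp)
    fc <- file.path(dir, paste0(acc, ".cds.fasta"))
    write_fasta(sim$cds[gm$gene_id], fc)
    paths <- c(paths, p, fp, fc)
  }
  pd <- file.path(dir, "domains.tsv")
  utils::write.table(sim$domains, pd, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tog <- data.frame(gene_id = names(sim$truth$og_of_gene),
                    og = unname(sim$truth$og_of_gene),
                    architecture = unname(sim$truth$architecture))
  pt <- file.path(dir, "truth_og.tsv")
  utils::write.table(tog, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- file.path(dir, "truth_pairs.tsv")
  utils::write.table(sim$truth$pairs, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$config
  yml <- file.path(dir, "config.yaml")
  writeLines(c(
    paste0("n_accessions: ", cfg$n_accessions),
    paste0("per_og_theta: ", cfg$per_og_theta),
    paste0("gene_conversion_rate: ", cfg$gene_conversion_rate),
    paste0("paralog_og_fraction: ", cfg$paralog_og_fraction),
    paste0("id_gene_fraction: ", cfg$id_gene_fraction),
    paste0("pair_fraction: ", cfg$pair_fraction),
    paste0("cluster_window: ", cfg$cluster_window),
    paste0("seed: ", cfg$seed)), yml)
  invisible(c(paths, pd, pt, pp, yml))
}
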