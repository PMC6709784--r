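#' Pipeline configuration
#'
#' All thresholds of the pan-NLRome construction pipeline in one place,
#' at their standard values: cloud/shell/core size bounds 12/51, the 5%
#' paralog rule, the 200-kb physical cluster window, the 10-kb
#' head-to-head separation bound, the 10-accession co-occurrence
#' threshold, MCL inflation 1.5, minimum orthogroup size 2, 1000x/100x
#' rarefaction, a 2-of-3 coiled-coil vote and a 0.1 enrichment q-value
#' cutoff.
#'
#' @param cloud_max,shell_max orthogroup size bounds (cloud <= 12,
#'   shell <= 51).
#' @param paralog_accession_fraction the 5% rule threshold.
#' @param cluster_window physical clustering window (bases).
#' @param pair_max_separation head-to-head 5' separation bound (bases).
#' @param cooccurrence_min_accessions co-occurrence edge threshold.
#' @param mcl_inflation MCL inflation exponent.
#' @param og_min_size minimum orthogroup size.
#' @param rarefaction_reps_og,rarefaction_reps_div rarefaction replicate
#'   counts for discovery and diversity curves.
#' @param tree_bootstrap_reps column-bootstrap replicates per gene tree.
#' @param cc_vote_min predictors required for a consensus coiled-coil.
#' @param enrichment_q_max BH q-value threshold for flag enrichment.
#' @param seed integer seed for every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cloud_max = 12L, shell_max = 51L,
                            paralog_accession_fraction = 0.05,
                            cluster_window = 200000,
                            pair_max_separation = 10000,
                            cooccurrence_min_accessions = 10L,
                            mcl_inflation = 1.5, og_min_size = 2L,
                            rarefaction_reps_og = 1000L,
                            rarefaction_reps_div = 100L,
                            tree_bootstrap_reps = 100L,
                            cc_vote_min = 2L, enrichment_q_max = 0.1,
                            seed = 1L) {
  if (cloud_max >= shell_max) stop("cloud_max must be below shell_max")
  vals <- list(cloud_max = cloud_max, shell_max = shell_max,
               paralog_accession_fraction = paralog_accession_fraction,
               cluster_window = cluster_window,
               pair_max_separation = pair_max_separation,
               cooccurrence_min_accessions = cooccurrence_min_accessions,
               mcl_inflation = mcl_inflation, og_min_size = og_min_size,
               rarefaction_reps_og = rarefaction_reps_og,
               rarefaction_reps_div = rarefaction_reps_div,
               tree_bootstrap_reps = tree_bootstrap_reps,
               cc_vote_min = cc_vote_min,
               enrichment_q_max = enrichment_q_max,
               seed = as.integer(seed))
  num <- unlist(vals[setdiff(names(vals), "seed")])
  if (any(num <= 0)) stop("all thresholds must be positive")
  structure(vals, class = "pipeline_config")
}

stage_log <- function(verbose, ...) if (verbose) message("[pannlrome] ", ...)

#' Run the full pan-NLRome pipeline
#'
#' Orchestrates simulate (or read) -> classify -> cluster -> refine ->
#' stats -> saturate -> anchor -> report, logging gene and orthogroup
#' counts at each stage.
#'
#' @param config a [pipeline_config()].
#' @param sim_config a [simulation_config()] used when `panel` is NULL.
#' @param panel optional panel list (as from [read_panel()] or a
#'   `pannlrome_sim`) to analyze instead of simulating.
#' @param out_dir optional directory for report TSVs.
#' @param verbose log stage progress (default TRUE).
#' @return a list report with elements `panel`, `classification`, `edges`,
#'   `ogs`, `refined` (membership list), `og_log`, `og_table`, `stats`,
#'   `domain_stats`, `enrichment`, `presence`, `rarefaction`,
#'   `saturation_size`, `diversity_rarefaction`, `cooccurrence`,
#'   `anchoring`, `pairs`, `clusters`, `trees`, `alignments`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         sim_config = simulation_config(),
                         panel = NULL, out_dir = NULL, verbose = TRUE) {
  set.seed(config$seed)
  if (is.null(panel)) {
    stage_log(verbose, "simulate: generating synthetic panel")
    panel <- simulate_pannlrome(sim_config)
  }
  genes <- panel$genes
  stage_log(verbose, "input: ", nrow(genes), " genes, ",
            length(unique(genes$accession)), " accessions")

  # classify -------------------------------------------------------------
  cls <- classify_genes(panel$domains, cc_min_votes = config$cc_vote_min)
  nlr_genes <- cls$gene_id[cls$is_nlr]
  stage_log(verbose, "classify: ", length(nlr_genes), " NLRs / ",
            nrow(cls), " genes")
  acc_of <- setNames(genes$accession, genes$gene_id)
  ids <- find_integrated_domains(panel$domains, acc_of, nlr_genes)

  # cluster --------------------------------------------------------------
  edges <- pairwise_similarity(panel$proteins[nlr_genes])
  typed <- classify_edges(edges, acc_of)
  clusters <- mcl_cluster(typed, inflation = config$mcl_inflation)
  og0 <- form_ogs(clusters, all_genes = nlr_genes,
                  min_og_size = config$og_min_size)
  stage_log(verbose, "cluster: ", length(og0$ogs), " orthogroups, ",
            length(og0$singletons), " singletons (",
            nrow(typed), " typed edges)")

  # refine ---------------------------------------------------------------
  refined <- list(); og_log <- list()
  alignments <- list(); trees <- list()
  for (og in names(og0$ogs)) {
    members <- og0$ogs[[og]]
    if (length(members) > 4L) {
      msa <- align_og(panel$proteins[members])
      outl <- detect_outliers(msa, bootstrap_reps = 100L)
      log_rows <- NULL
      if (length(outl)) {
        log_rows <- data.frame(gene_id = outl, status = "outlier")
        members <- setdiff(members, outl)
        msa <- align_og(panel$proteins[members])
      }
      caln <- protein_to_codon(msa, panel$cds)
      tr <- build_tree(caln, bootstrap_reps = config$tree_bootstrap_reps)
      res <- refine_og(og, members, tr, acc_of,
                       config$paralog_accession_fraction)
      res$log <- rbind(log_rows, res$log)
    } else {
      msa <- align_og(panel$proteins[members])
      caln <- protein_to_codon(msa, panel$cds)
      res <- list(ogs = setNames(list(members), og),
                  log = data.frame(gene_id = members, status = "kept"))
    }
    og_log[[og]] <- res$log
    for (nid in names(res$ogs)) {
      mem <- res$ogs[[nid]]
      refined[[nid]] <- mem
      sub <- as_aln_matrix(caln)[mem, , drop = FALSE]
      # drop all-gap codon columns left by removed members
      cod <- which(colSums(sub != "-") > 0L)
      keep_cod <- unique((cod - 1L) %/% 3L + 1L)
      cols <- c(rbind(3L * keep_cod - 2L, 3L * keep_cod - 1L,
                      3L * keep_cod))
      alignments[[nid]] <- codon_alignment(sub[, sort(cols),
                                               drop = FALSE])
      trees[[nid]] <- build_tree(alignments[[nid]], bootstrap_reps = 0L)
    }
  }
  stage_log(verbose, "refine: ", length(refined), " refined orthogroups")

  # physical organization and per-gene metadata --------------------------
  phys <- detect_physical_clusters(genes, window = config$cluster_window)
  prs <- detect_pairs(genes, max_separation = config$pair_max_separation)
  paired_genes <- unique(c(prs$gene_left, prs$gene_right))
  meta <- data.frame(
    gene_id = cls$gene_id, class = cls$class, has_id = cls$has_id,
    clustered = phys$clustered[match(cls$gene_id, phys$gene_id)],
    paired = cls$gene_id %in% paired_genes)

  # annotate and per-orthogroup statistics -------------------------------
  dom_levels <- c("NB", "TIR", "RPW8", "LRR", "CC")
  og_rows <- list(); stat_rows <- list(); dstat_rows <- list()
  consensus_domains <- consensus_domain_table(panel$domains,
                                              config$cc_vote_min)
  for (nid in names(refined)) {
    mem <- refined[[nid]]
    og_rows[[nid]] <- annotate_og(nid, mem, meta, trees[[nid]])
    st <- neutrality_stats(alignments[[nid]])
    stat_rows[[nid]] <- cbind(og_id = nid, as.data.frame(
      unclass(st)[c("n", "L", "S", "pi", "theta_w", "K", "hap_div",
                    "tajima_d", "fu_li_d_star", "fu_li_f_star", "r2",
                    "strobeck_s")]))
    labs <- annotate_columns(alignments[[nid]], consensus_domains)
    for (dm in intersect(dom_levels, unique(labs))) {
      ds <- domain_subset_stats(alignments[[nid]], labs, dm)
      dstat_rows[[paste(nid, dm)]] <- data.frame(
        og_id = nid, domain = dm, L = ds$L, S = ds$S, pi = ds$pi,
        hap_div = ds$hap_div, tajima_d = ds$tajima_d)
    }
  }
  og_table <- do.call(rbind, og_rows)
  stats <- do.call(rbind, stat_rows)
  domain_stats <- do.call(rbind, dstat_rows)
  rownames(og_table) <- rownames(stats) <- NULL
  stage_log(verbose, "stats: ",
            paste(names(table(og_table$og_type)),
                  table(og_table$og_type), collapse = " ", sep = "="))

  # flag enrichment -------------------------------------------------------
  gene_flags <- flag_table(genes, meta)
  enr <- if (nrow(gene_flags))
    flag_enrichment(refined, gene_flags,
                    universe = nlr_genes, q_max = config$enrichment_q_max)
  else NULL

  # saturation ------------------------------------------------------------
  accs <- sort(unique(genes$accession))
  presence <- presence_matrix(refined, acc_of, accs)
  rar <- rarefy_ogs(presence, reps = config$rarefaction_reps_og)
  sat <- saturation_point(rar, target = 0.95)
  divr <- rarefy_diversity(alignments, acc_of,
                           reps = config$rarefaction_reps_div)
  stage_log(verbose, "saturate: 95% of orthogroups at ", sat,
            " accessions")

  # anchoring -------------------------------------------------------------
  og_of_gene <- setNames(rep(names(refined), lengths(refined)),
                         unlist(refined, use.names = FALSE))
  assignments <- data.frame(
    gene_id = genes$gene_id, accession = genes$accession,
    contig = genes$contig,
    og_id = og_of_gene[genes$gene_id])
  ref_acc <- accs[1L]
  ref_int <- vapply(names(refined), function(nid) {
    g <- refined[[nid]][acc_of[refined[[nid]]] == ref_acc]
    if (!length(g)) return(NA_character_)
    i <- match(g[1L], genes$gene_id)
    sprintf("%s:%d-%d", genes$contig[i], genes$start[i], genes$end[i])
  }, character(1L))
  og_attrs <- data.frame(og_id = names(refined),
                         size = lengths(refined),
                         is_nlr = TRUE,
                         reference_interval = unname(ref_int))
  graph <- build_cooccurrence(assignments, og_attrs)
  nets <- subnetworks(graph, config$cooccurrence_min_accessions)
  anch <- anchor_nonreference(nets)
  stage_log(verbose, "anchor: ", nrow(anch), " non-reference orthogroups",
            " anchored via ", length(nets), " subnetworks")

  report <- list(
    panel = panel, classification = cls, integrated_domains = ids,
    edges = typed, ogs = og0, refined = refined,
    og_log = do.call(rbind, c(og_log, make.row.names = FALSE)),
    og_table = og_table, stats = stats, domain_stats = domain_stats,
    enrichment = enr, presence = presence, rarefaction = rar,
    saturation_size = sat, diversity_rarefaction = divr,
    cooccurrence = graph, anchoring = anch, pairs = prs,
    clusters = phys, trees = trees, alignments = alignments,
    meta = meta, config = config)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# consensus-CC-resolved domain table for column annotation
consensus_domain_table <- function(domains, cc_min_votes = 2L) {
  domains$label <- canonicalize_domain(domains$label)
  cc_sources <- c("coils", "paircoil", "nlrparser")
  is_cc <- domains$label == "CC" & domains$source %in% cc_sources
  base <- domains[!is_cc, c("gene_id", "label", "start", "end")]
  cc <- domains[is_cc, , drop = FALSE]
  if (nrow(cc)) {
    cons <- lapply(split(cc, cc$gene_id), function(d) {
      v <- vote_cc(d, min_votes = cc_min_votes)
      if (!nrow(v)) return(NULL)
      data.frame(gene_id = d$gene_id[1L], label = "CC",
                 start = v$start, end = v$end)
    })
    base <- rbind(base, do.call(rbind, cons))
  }
  rownames(base) <- NULL
  base
}

# long table of per-gene flags (annotation flags plus computed
# paired/clustered status)
flag_table <- function(genes, meta) {
  ann <- genes[nzchar(genes$flags), c("gene_id", "flags")]
  rows <- if (nrow(ann)) {
    fl <- strsplit(ann$flags, ",")
    data.frame(gene_id = rep(ann$gene_id, lengths(fl)),
               flag = unlist(fl, use.names = FALSE))
  } else data.frame(gene_id = character(), flag = character())
  rbind(rows,
        data.frame(gene_id = meta$gene_id[meta$paired %in% TRUE],
                   flag = "paired"),
        data.frame(gene_id = meta$gene_id[meta$clustered %in% TRUE],
                   flag = "clustered"))
}

presence_matrix <- function(og_members, accession_of_gene, accessions) {
  M <- matrix(0L, length(og_members), length(accessions),
              dimnames = list(names(og_members), accessions))
  for (og in names(og_members)) {
    tb <- table(accession_of_gene[og_members[[og]]])
    M[og, names(tb)] <- as.integer(tb)
  }
  M
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(report$classification, "classification.tsv")
  wt(report$og_table, "og_table.tsv")
  wt(report$stats, "og_stats.tsv")
  if (!is.null(report$domain_stats)) wt(report$domain_stats,
                                        "domain_stats.tsv")
  if (!is.null(report$enrichment)) wt(report$enrichment,
                                      "enrichment.tsv")
  wt(report$rarefaction, "rarefaction.tsv")
  wt(report$diversity_rarefaction, "diversity_rarefaction.tsv")
  wt(report$anchoring, "anchoring.tsv")
  wt(report$pairs, "pairs.tsv")
  wt(report$og_log, "refinement_log.tsv")
  mem <- data.frame(og_id = rep(names(report$refined),
                                lengths(report$refined)),
                    gene_id = unlist(report$refined, use.names = FALSE))
  wt(mem, "og_members.tsv")
  ed <- igraph::as_data_frame(report$cooccurrence, what = "edges")
  wt(ed, "cooccurrence_edges.tsv")
  for (nid in names(report$trees))
    write_newick(report$trees[[nid]],
                 file.path(out_dir, paste0(nid, ".nwk")))
  invisible(out_dir)
}
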