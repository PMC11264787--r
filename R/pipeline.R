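# End-to-end pipeline: phenotypes -> preprocess -> network -> association ->
# mediation -> integration -> eqtl, with per-stage outputs, a run manifest
# and one log line per stage. Deterministic for a fixed config and seed.

# analysis traits entering the primary module-trait models (indexed set)
primary_traits <- c("taci_z", "si_z", "ci_z", "svri_z", "pwv_z", "rsh_z",
                    "wmh_burden_z")

#' Run the full analysis pipeline
#'
#' Executes the stages in order on either synthetic data (generated from
#' `sim` when `config$paths` has no inputs) or on files named in
#' `config$paths` (`mirna_counts`, `gene_counts`, `samples`, `predictions`;
#' genotype inputs are only available synthetically or via a prebuilt `geno`
#' list). Each stage writes its output tables to `outdir` and one manifest
#' line; any stage failure aborts with the stage name and cause.
#'
#' @param config configuration list from [default_config()] /
#'   [read_config()].
#' @param outdir output directory (created if absent).
#' @param sim optional [sim_spec()] for synthetic input generation; its seed
#'   is forced to `config$seed`.
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("mirvasc_"),
                         sim = sim_spec()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log <<- c(log, line)
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop_mv("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  out <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    name
  }
  files <- character(0)

  # --- inputs ---------------------------------------------------------------
  inputs <- stage("inputs", {
    pth <- config$paths
    if (length(pth) && !is.null(pth$samples)) {
      if (!file.exists(pth$samples))
        stop_mv("phenotype file not found: %s", pth$samples)
      list(
        mirna_counts = read_count_matrix(pth$mirna_counts),
        gene_counts = if (!is.null(pth$gene_counts))
          read_count_matrix(pth$gene_counts) else NULL,
        samples = read_sample_table(pth$samples),
        predictions = if (!is.null(pth$predictions))
          utils::read.delim(pth$predictions, stringsAsFactors = FALSE) else NULL,
        term_sets = if (!is.null(pth$gmt)) read_gmt(pth$gmt) else NULL,
        genotypes = NULL, synthetic = FALSE)
    } else {
      sim$seed <- config$seed
      c(simulate_cohort(sim), list(synthetic = TRUE))
    }
  })
  note("inputs: %d miRNAs x %d samples%s", nrow(inputs$mirna_counts),
       ncol(inputs$mirna_counts),
       if (inputs$synthetic) " (synthetic)" else "")
  if (inputs$synthetic) {
    write_ground_truth(inputs$truth, file.path(outdir, "ground_truth.json"))
    files <- c(files, "ground_truth.json")
  }

  # --- phenotypes -----------------------------------------------------------
  traits <- stage("phenotypes", transform_traits(build_trait_table(inputs$samples)))
  files <- c(files, out(traits, "traits.tsv"))
  note("phenotypes: derived %d trait columns for %d samples",
       ncol(traits) - 1, nrow(traits))

  # --- preprocess -----------------------------------------------------------
  covars <- data.frame(age = inputs$samples$age, sex = inputs$samples$sex)
  batch <- data.frame(batch = factor(inputs$samples$batch))
  prep <- stage("preprocess", {
    flt <- filter_features(inputs$mirna_counts, config$filter$min_mean,
                           config$filter$min_prop)
    expr <- residualize(normalize_counts(flt), batch)
    gexpr <- NULL
    if (!is.null(inputs$gene_counts)) {
      gflt <- filter_features(inputs$gene_counts, config$filter$min_mean,
                              config$filter$min_prop)
      gexpr <- residualize(normalize_counts(gflt), batch)
    }
    list(expr = expr, gene_expr = gexpr)
  })
  note("preprocess: %d of %d miRNAs retained after filtering",
       nrow(prep$expr), nrow(inputs$mirna_counts))

  # --- network --------------------------------------------------------------
  net <- stage("network", build_network(prep$expr, config$network))
  part <- net$partition
  files <- c(files, out(data.frame(
    mirna = names(part$labels), module = part$labels, color = part$colors,
    part$mm, check.names = FALSE), "module_labels.tsv"))
  files <- c(files, out(data.frame(sample_id = rownames(part$eigen),
                                   part$eigen, check.names = FALSE),
                        "eigen.tsv"))
  if (!is.null(net$power_fit))
    files <- c(files, out(net$power_fit, "power_fit.tsv"))
  note("network: power %d, %d modules (sizes %s), %d unassigned",
       net$power, length(part$sizes),
       paste(part$sizes, collapse = "/"), sum(part$labels == 0))

  # --- association ----------------------------------------------------------
  assoc <- stage("association", {
    tt <- traits[match(colnames(prep$expr), traits$sample_id),
                 intersect(primary_traits, names(traits)), drop = FALSE]
    ma <- associate_modules(part$eigen, tt, covars)
    keys <- key_modules(ma, config$association$fdr_lenient)
    exploratory <- FALSE
    if (!nrow(keys)) {
      # exploratory fallback so downstream stages remain exercised
      keys <- ma[which.min(ma$p), c("predictor", "trait", "beta", "p", "q")]
      exploratory <- TRUE
    }
    mirna_rows <- list()
    for (mod in unique(keys$predictor)) {
      members <- names(part$labels)[part$colors == mod]
      for (tr in unique(keys$trait[keys$predictor == mod])) {
        for (f in members) {
          mirna_rows[[length(mirna_rows) + 1]] <-
            associate(prep$expr[f, ], tt[[tr]], covars,
                      predictor_id = f, trait_id = tr, model_tag = "mirna")
        }
      }
    }
    mirna_assoc <- do.call(rbind, mirna_rows)
    hubs <- select_hubs(part, mirna_assoc, keys,
                        config$hub$mm_thresh, config$hub$p_thresh)
    sens <- sensitivity_non_indexed(part$eigen,
                                    traits[match(colnames(prep$expr),
                                                 traits$sample_id), ],
                                    covars, traits$bmi[match(colnames(prep$expr),
                                                             traits$sample_id)])
    list(module_assoc = ma, keys = keys, exploratory = exploratory,
         mirna_assoc = mirna_assoc, hubs = hubs, sensitivity = sens, tt = tt)
  })
  files <- c(files, out(assoc$module_assoc, "module_assoc.tsv"),
             out(assoc$keys, "key_modules.tsv"),
             out(assoc$mirna_assoc, "mirna_assoc.tsv"),
             out(assoc$hubs, "hubs.tsv"),
             out(assoc$sensitivity, "sensitivity_non_indexed.tsv"))
  note("association: %d module-trait tests, %d key pairs%s, %d hubs",
       nrow(assoc$module_assoc), nrow(assoc$keys),
       if (assoc$exploratory) " (exploratory fallback)" else "",
       nrow(assoc$hubs))

  # --- mediation ------------------------------------------------------------
  med <- stage("mediation", {
    if (!"wmh_burden_z" %in% names(assoc$tt) ||
        !"taci_z" %in% names(assoc$tt) || !nrow(assoc$hubs)) NULL else {
      mod <- assoc$hubs$module[1]
      exposures <- c(
        stats::setNames(list(part$eigen[, mod]), paste0("eigen_", mod)),
        stats::setNames(lapply(assoc$hubs$mirna[assoc$hubs$module == mod],
                               function(f) prep$expr[f, ]),
                        assoc$hubs$mirna[assoc$hubs$module == mod]))
      mediation_suite(exposures, assoc$tt$taci_z, assoc$tt$wmh_burden_z,
                      covars, n_boot = config$mediation$n_boot,
                      seed = substream_seed(config$seed, "mediation"))
    }
  })
  if (!is.null(med)) {
    files <- c(files, out(med, "mediation.tsv"))
    note("mediation: %d exposures, %d suppressed", nrow(med), sum(med$suppressed))
  } else note("mediation: skipped (no hubs or traits missing)")

  # --- integration ----------------------------------------------------------
  integ <- stage("integration", {
    if (is.null(prep$gene_expr) || is.null(inputs$predictions)) NULL else {
    cellcov <- cbind(covars, inputs$samples[c("ery", "leu", "plt")])
    conf <- confirm_targets(inputs$predictions, prep$expr, prep$gene_expr,
                            cellcov)
    sets <- split(conf$pairs$gene[conf$pairs$confirmed],
                  conf$pairs$mirna[conf$pairs$confirmed])
    ovl <- if (length(sets) >= 2) target_overlap(sets) else NULL
    enr <- NULL
    if (!is.null(inputs$term_sets)) {
      hits <- unique(unlist(sets))
      he <- hypergeom_enrich(hits, inputs$term_sets, rownames(prep$gene_expr))
      enr <- semantic_aggregate(he, term_sets = inputs$term_sets)
    }
    list(confirm = conf, overlap = ovl, enrich = enr)
    }
  })
  if (!is.null(integ)) {
    files <- c(files, out(integ$confirm$pairs, "target_pairs.tsv"),
               out(integ$confirm$summary, "target_summary.tsv"))
    if (!is.null(integ$overlap))
      files <- c(files, out(integ$overlap, "target_overlap.tsv"))
    if (!is.null(integ$enrich))
      files <- c(files, out(integ$enrich$groups, "enrichment_groups.tsv"))
    note("integration: %d pairs tested, %d confirmed",
         nrow(integ$confirm$pairs), sum(integ$confirm$pairs$confirmed))
  } else note("integration: skipped (no gene expression or predictions)")

  # --- eqtl -----------------------------------------------------------------
  eq <- stage("eqtl", {
    if (is.null(inputs$genotypes)) NULL else {
    targets <- if (nrow(assoc$hubs)) unique(assoc$hubs$mirna) else
      rownames(prep$expr)[1]
    targets <- intersect(targets, rownames(prep$expr))
    resid <- residualize_for_eqtl(
      prep$expr[targets, , drop = FALSE],
      cbind(covars, batch), inputs$genotypes$dosages[colnames(prep$expr), ,
                                                    drop = FALSE],
      n_pc = config$eqtl$n_pc)
    hits <- eqtl_scan(inputs$genotypes, resid, alpha = config$eqtl$alpha,
                      cis_window = config$eqtl$cis_window)
    loci <- if (nrow(hits)) clump_loci(hits, inputs$genotypes,
                                       config$eqtl$r2_locus,
                                       config$eqtl$r2_lead) else NULL
    list(hits = hits, loci = loci)
    }
  })
  if (!is.null(eq)) {
    files <- c(files, out(eq$hits, "eqtl_hits.tsv"))
    if (!is.null(eq$loci)) files <- c(files, out(eq$loci, "eqtl_loci.tsv"))
    note("eqtl: %d significant SNP-miRNA pairs, %d loci", nrow(eq$hits),
         if (is.null(eq$loci)) 0L else nrow(eq$loci))
  } else note("eqtl: skipped (no genotypes)")

  # --- manifest -------------------------------------------------------------
  write_config(config, file.path(outdir, "config.yaml"))
  manifest <- list(seed = config$seed, synthetic = inputs$synthetic,
                   n_samples = ncol(inputs$mirna_counts),
                   n_mirna_input = nrow(inputs$mirna_counts),
                   n_mirna_filtered = nrow(prep$expr),
                   n_modules = length(part$sizes),
                   power = net$power, files = c(files, "config.yaml"),
                   log = log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(inputs = inputs, traits = traits, prep = prep, net = net,
                 assoc = assoc, mediation = med, integration = integ,
                 eqtl = eq, manifest = manifest, outdir = outdir))
}
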