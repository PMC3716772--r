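#' Pipeline configuration
#'
#' Assembles and validates the full parameter set of [run_all()].  All
#' module parameters carry their documented defaults; unknown keys are
#' rejected so that typos cannot silently fall back to defaults.
#'
#' @param input_dir optional dataset directory ([write_dataset()] layout);
#'   when NULL, a synthetic panel is generated from `synth`.
#' @param synth list of [sim_config()] overrides for the synthetic run.
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param genecall,ortho,panmatrix,pseudoasm,plasmids,trees,crispr,gtm
#'   per-module parameter lists (see each module's functions).
#' @param write_dataset also write the generated dataset under
#'   `out_dir/dataset`.
#' @return object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, synth = list(),
                       out_dir = tempfile("panforge_run_"), seed = 1,
                       genecall = list(), ortho = list(),
                       panmatrix = list(), pseudoasm = list(),
                       plasmids = list(), trees = list(),
                       crispr = list(), gtm = list(),
                       write_dataset = FALSE) {
  cfg <- list(input_dir = input_dir, synth = synth, out_dir = out_dir,
              seed = seed, genecall = genecall, ortho = ortho,
              panmatrix = panmatrix, pseudoasm = pseudoasm,
              plasmids = plasmids, trees = trees, crispr = crispr,
              gtm = gtm, write_dataset = write_dataset)
  validate_config(cfg)
}

config_defaults <- function() {
  list(input_dir = NULL, synth = list(),
       out_dir = NULL, seed = 1,
       genecall = list(min_support_fraction = 0.5, max_overlap = 100),
       ortho = list(inflation = 1.5, k = 4, min_shared_kmers = 8,
                    score_cutoff = 50, id_cutoff = 0.4, cov_cutoff = 0.5),
       panmatrix = list(include_singletons = FALSE, n_permutations = 100,
                        min_run = 10, max_presence = 0.9,
                        cassette_min_fraction = 0.8),
       pseudoasm = list(window = 5000, step = 1000),
       plasmids = list(chrom_map_cutoff = 0.2, known_cov_cutoff = 0.5,
                       known_id_cutoff = 0.8, min_overlap = 50),
       trees = list(linkage = "average"),
       crispr = list(min_repeats = 3, max_repeat_mismatch = 1),
       gtm = list(n_trees = 1000, importance_threshold = 0.005,
                  od_threshold = 0.8),
       write_dataset = FALSE)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; fills defaults, rejects unknown
#' keys (naming them) and checks parameter ranges.
#'
#' @param config YAML path or (partial) configuration list.
#' @return a complete `run_config` object.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  sections <- c("genecall", "ortho", "panmatrix", "pseudoasm",
                "plasmids", "trees", "crispr", "gtm")
  for (sec in sections) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  cfg <- defaults
  for (nm in names(config)) {
    cfg[[nm]] <- if (nm %in% sections) {
      modifyList(defaults[[nm]], config[[nm]])
    } else config[[nm]]
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempfile("panforge_run_")
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir)) {
    stop("input_dir does not exist: ", cfg$input_dir)
  }
  if (cfg$ortho$inflation <= 0) {
    stop("ortho inflation must be positive, got ", cfg$ortho$inflation)
  }
  if (cfg$panmatrix$n_permutations < 1) {
    stop("panmatrix n_permutations must be >= 1")
  }
  for (p in c("max_presence", "cassette_min_fraction")) {
    v <- cfg$panmatrix[[p]]
    if (v < 0 || v > 1) stop("panmatrix ", p, " must be in [0, 1]")
  }
  if (cfg$genecall$min_support_fraction < 0 ||
      cfg$genecall$min_support_fraction > 1) {
    stop("genecall min_support_fraction must be in [0, 1]")
  }
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

run_stage <- function(stage, expr) {
  stage_log(stage, "start")
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pan-genome pipeline
#'
#' Executes all stages in dependency order: dataset (simulate or read) ->
#' consensus gene calling -> ortholog clustering -> presence/absence
#' matrix and accumulation curves -> pseudo-assembly and GC tracks ->
#' plasmid classification -> strain trees -> CRISPR scan and typing ->
#' gene-trait matching.  All tabular outputs are written as TSV under
#' `config$out_dir`, trees as Newick, and a manifest (package version,
#' seed, parameters, per-file MD5 checksums) as JSON.  A failing stage
#' aborts with the stage name; outputs of completed stages are retained.
#' Missing phenotype data skips the GTM stage with a warning.
#'
#' @param config a `run_config` (or list / YAML path accepted by
#'   [validate_config()]).
#' @return result bundle (list) with all stage outputs and the manifest.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write_tsv(df, p)
    outputs <<- c(outputs, p)
    p
  }

  ## dataset ----------------------------------------------------------------
  ds <- run_stage("dataset", {
    if (is.null(cfg$input_dir)) {
      sc <- do.call(sim_config, modifyList(list(seed = cfg$seed),
                                           cfg$synth))
      sim <- simulate_pangenome(sc)
      od <- if (!is.null(sim$truth$phenotype_labels)) {
        simulate_growth_curves(sim$truth, seed = cfg$seed + 1L)
      } else NULL
      if (cfg$write_dataset) {
        write_dataset(sim, file.path(cfg$out_dir, "dataset"), od = od)
      }
      list(strains = sim$strains, genomes = sim$genomes,
           genes = sim$genes, proteins = sim$proteins,
           tracks = sim$tracks, reference = sim$reference,
           known_plasmids = sim$known_plasmids, od = od,
           truth = sim$truth)
    } else {
      d <- read_dataset(cfg$input_dir)
      list(strains = d$strains, genomes = d$genomes, genes = d$genes,
           proteins = d$proteins, tracks = d$tracks,
           reference = d$reference, known_plasmids = d$known_plasmids,
           od = d$od, truth = d$truth)
    }
  })

  ## consensus gene calling --------------------------------------------------
  cons <- run_stage("genecall", {
    res <- list()
    for (s in ds$strains) {
      res[[s]] <- call_genes(ds$tracks[[s]], ds$genomes[[s]], strain = s,
                             n_predictors = length(ds$tracks[[s]]),
                             min_support_fraction =
                               cfg$genecall$min_support_fraction,
                             max_overlap = cfg$genecall$max_overlap)
    }
    genes <- do.call(rbind, lapply(res, `[[`, "genes"))
    rownames(genes) <- NULL
    proteins <- do.call(c, unname(lapply(res, `[[`, "proteins")))
    discards <- do.call(rbind, lapply(names(res), function(s)
      if (nrow(res[[s]]$discards) > 0) cbind(strain = s,
                                             res[[s]]$discards) else NULL))
    # transfer per-gene annotations from the dataset's annotation track
    # (stop-anchored match, as annotation follows the gene not the start)
    key <- function(d) paste(d$contig, ifelse(d$strand == "+", d$end,
                                              d$start), d$strand)
    ann_map <- setNames(ds$genes$annotation, key(ds$genes))
    genes$annotation <- unname(ann_map[key(genes)])
    emit(genes, "consensus_genes.tsv")
    if (!is.null(discards)) emit(discards, "discard_log.tsv")
    list(genes = genes, proteins = proteins, discards = discards)
  })

  ## ortholog clustering -----------------------------------------------------
  ogs <- run_stage("ortho", {
    o <- infer_orthologs(
      cons$proteins,
      annotations = setNames(cons$genes$annotation, cons$genes$gene_id),
      inflation = cfg$ortho$inflation, k = cfg$ortho$k,
      min_shared_kmers = cfg$ortho$min_shared_kmers,
      score_cutoff = cfg$ortho$score_cutoff,
      id_cutoff = cfg$ortho$id_cutoff, cov_cutoff = cfg$ortho$cov_cutoff)
    emit(o$og, "ogs.tsv")
    emit(data.frame(og_id = rep(names(o$members), lengths(o$members)),
                    gene_id = unlist(o$members), row.names = NULL),
         "og_members.tsv")
    o
  })

  ## presence/absence matrix -------------------------------------------------
  pan <- run_stage("panmatrix", {
    pm <- build_matrix(ogs, include_singletons =
                         cfg$panmatrix$include_singletons)
    curves <- accumulation_curves(pm,
                                  n_permutations =
                                    cfg$panmatrix$n_permutations,
                                  seed = cfg$seed + 2L)
    scc <- single_copy_core(pm)
    emit(cbind(data.frame(og_id = rownames(pm$mat)),
               as.data.frame(pm$mat)), "matrix.tsv")
    emit(curves$summary, "curves.tsv")
    writeLines(scc, file.path(cfg$out_dir, "single_copy_core.txt"))
    outputs <- c(outputs, file.path(cfg$out_dir, "single_copy_core.txt"))
    list(pm = pm, curves = curves, single_copy_core = scc)
  })

  ## pseudo-assembly ---------------------------------------------------------
  pa <- run_stage("pseudoasm", {
    p <- pseudo_assemble(cons$genes, cons$proteins, ds$reference,
                         ds$genomes, ogs = ogs,
                         k = cfg$ortho$k,
                         min_shared_kmers = cfg$ortho$min_shared_kmers,
                         score_cutoff = cfg$ortho$score_cutoff,
                         id_cutoff = cfg$ortho$id_cutoff,
                         cov_cutoff = cfg$ortho$cov_cutoff)
    emit(p$orders, "pseudoassembly.tsv")
    gc_tracks <- do.call(rbind, lapply(ds$strains, function(s) {
      ord <- p$orders$contig[p$orders$strain == s]
      cbind(strain = s, gc_profile(ds$genomes[[s]][ord],
                                   window = cfg$pseudoasm$window,
                                   step = cfg$pseudoasm$step))
    }))
    emit(gc_tracks, "gc_track.tsv")
    regions <- find_variable_regions(pan$pm, p$og_ranks,
                                     min_run = cfg$panmatrix$min_run,
                                     max_presence =
                                       cfg$panmatrix$max_presence)
    emit(regions, "variable_regions.tsv")
    cassettes <- NULL
    if (nrow(regions) > 0) {
      cas_list <- setNames(strsplit(regions$og_ids, ",", fixed = TRUE),
                           sprintf("region_%d", regions$region))
      cassettes <- cassette_presence(pan$pm, cas_list,
                                     min_fraction =
                                       cfg$panmatrix$cassette_min_fraction)
      emit(cbind(data.frame(cassette = rownames(cassettes)),
                 as.data.frame(cassettes)), "cassettes.tsv")
    }
    list(assembly = p, gc = gc_tracks, regions = regions,
         cassettes = cassettes)
  })

  ## plasmid classification --------------------------------------------------
  plas <- run_stage("plasmids", {
    ref_mapped <- unique(pa$assembly$anchors$gene_id)
    pc <- classify_plasmids(ds$genomes, cons$genes, ref_mapped,
                            setNames(cons$genes$annotation,
                                     cons$genes$gene_id),
                            ds$known_plasmids, ogs = ogs,
                            chrom_map_cutoff =
                              cfg$plasmids$chrom_map_cutoff,
                            known_cov_cutoff =
                              cfg$plasmids$known_cov_cutoff,
                            known_id_cutoff = cfg$plasmids$known_id_cutoff,
                            min_overlap = cfg$plasmids$min_overlap)
    emit(pc$evidence, "plasmids.tsv")
    writeLines(pc$plasmid_ogs, file.path(cfg$out_dir, "plasmid_ogs.txt"))
    outputs <- c(outputs, file.path(cfg$out_dir, "plasmid_ogs.txt"))
    pc
  })

  ## strain trees ------------------------------------------------------------
  trees <- run_stage("trees", {
    strain_of <- setNames(cons$genes$strain, cons$genes$gene_id)
    core_nwk <- NULL
    dm <- NULL
    if (length(pan$single_copy_core) >= 1 && length(ds$strains) >= 3) {
      dm <- core_distance(ogs, cons$proteins, strain_of,
                          og_ids = pan$single_copy_core)
      core_tree <- neighbor_joining(dm)
      core_nwk <- to_newick(core_tree)
      writeLines(core_nwk, file.path(cfg$out_dir, "core_tree.nwk"))
      emit(cbind(data.frame(strain = rownames(dm)), as.data.frame(dm)),
           "core_distance.tsv")
    }
    content <- content_tree(pan$pm, linkage = cfg$trees$linkage)
    content_nwk <- to_newick(content)
    writeLines(content_nwk, file.path(cfg$out_dir, "content_tree.nwk"))
    outputs <- c(outputs,
                 file.path(cfg$out_dir,
                           c("core_tree.nwk", "content_tree.nwk")))
    list(core_distance = dm, core_newick = core_nwk,
         content = content, content_newick = content_nwk)
  })

  ## CRISPR ------------------------------------------------------------------
  cr <- run_stage("crispr", {
    arrays <- scan_crispr(ds$genomes,
                          min_repeats = cfg$crispr$min_repeats,
                          max_repeat_mismatch =
                            cfg$crispr$max_repeat_mismatch)
    emit(arrays, "crispr_arrays.tsv")
    cat_sp <- catalog_spacers(arrays, strains = ds$strains)
    emit(cat_sp$spacers, "spacers.tsv")
    types <- assign_types(arrays, strains = ds$strains)
    emit(data.frame(strain = names(types$types),
                    crispr_type = unname(types$types)),
         "crispr_types.tsv")
    list(arrays = arrays, catalogue = cat_sp, types = types)
  })

  ## gene-trait matching -----------------------------------------------------
  gtm_res <- NULL
  if (is.null(ds$od)) {
    warning("no phenotype data: GTM stage skipped")
    stage_log("gtm", "skipped (no phenotype data)")
  } else {
    gtm_res <- run_stage("gtm", {
      phen <- call_growth(ds$od, threshold = cfg$gtm$od_threshold)
      emit(cbind(data.frame(strain = rownames(phen)),
                 as.data.frame(unclass(phen))), "phenotypes.tsv")
      rep <- gtm_report(pan$pm, phen,
                        n_trees = cfg$gtm$n_trees,
                        seed = cfg$seed + 3L,
                        importance_threshold =
                          cfg$gtm$importance_threshold,
                        annotation = setNames(ogs$og$annotation,
                                              ogs$og$og_id))
      paths <- write_gtm_report(rep, cfg$out_dir)
      outputs <- c(outputs, paths)
      list(phenotypes = phen, report = rep)
    })
  }

  ## manifest ----------------------------------------------------------------
  manifest <- run_stage("manifest", {
    files <- sort(unique(outputs))
    files <- files[file.exists(files)]
    man <- list(
      package = "panforge",
      version = as.character(packageVersion("panforge")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = cfg$seed,
      parameters = unclass(cfg),
      files = data.frame(
        file = basename(files),
        md5 = unname(tools::md5sum(files)),
        stringsAsFactors = FALSE))
    jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    man
  })
  stage_log("done", "all stages complete; outputs in ", cfg$out_dir)

  invisible(list(config = cfg, dataset = ds, consensus = cons, ogs = ogs,
                 pan = pan, pseudoassembly = pa, plasmids = plas,
                 trees = trees, crispr = cr, gtm = gtm_res,
                 manifest = manifest))
}
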