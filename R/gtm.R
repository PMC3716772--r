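#' Gene-trait matching (GTM)
#'
#' Associates OG presence/absence patterns with binary growth phenotypes
#' via Random-Forest feature importance: per trait, an ensemble of
#' decision trees is trained on the strains' OG presence vectors
#' (stratified bootstrap per tree, random feature subsets at each split);
#' per-OG importance is the normalized mean impurity (Gini) decrease,
#' scaled to sum to 1 over features.  OGs with importance strictly above
#' 0.005 are reported, coloured by their presence among the positive
#' (growth) class: >75% green (overrepresented), <25% red
#' (underrepresented), otherwise black.
#'
#' @name gtm
NULL

#' Call binary growth phenotypes from OD curves
#'
#' A strain grows on a sugar iff its blank-corrected OD exceeds the
#' threshold at any time point (strictly: an OD of exactly 0.8 is no
#' growth).  Blank correction subtracts the blank well's reading at the
#' same minute for the same sugar.
#'
#' @param od data.frame `strain`, `sugar`, `minute`, `od`; blank wells
#'   appear as strain `blank_strain`.
#' @param threshold growth threshold on blank-corrected OD.
#' @param blank_strain name of the blank pseudo-strain.
#' @return object of class `phenotype_table`: character matrix strain x
#'   sugar with entries `"growth"` / `"no_growth"` / `"missing"`.
#' @export
call_growth <- function(od, threshold = 0.8, blank_strain = "_blank") {
  strains <- sort(setdiff(unique(od$strain), blank_strain))
  sugars <- unique(od$sugar)
  out <- matrix("missing", length(strains), length(sugars),
                dimnames = list(strains, sugars))
  for (sg in sugars) {
    bl <- od[od$strain == blank_strain & od$sugar == sg, , drop = FALSE]
    blank_at <- setNames(bl$od, bl$minute)
    for (s in strains) {
      cur <- od[od$strain == s & od$sugar == sg, , drop = FALSE]
      if (nrow(cur) == 0) {
        message("no OD readings for ", s, " on ", sg, "; marked missing")
        next
      }
      corr <- cur$od - ifelse(is.na(blank_at[as.character(cur$minute)]),
                              0, blank_at[as.character(cur$minute)])
      out[s, sg] <- if (max(corr) > threshold) "growth" else "no_growth"
    }
  }
  structure(out, class = c("phenotype_table", class(out)))
}

#' Colour classification of a selected OG
#'
#' @param fraction presence fraction of the OG among the phenotype class.
#' @return `"green"` (>0.75), `"red"` (<0.25) or `"black"`.
#' @export
color_classify <- function(fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  ifelse(fraction > 0.75, "green",
         ifelse(fraction < 0.25, "red", "black"))
}

#' Random-Forest gene-trait matching for one trait
#'
#' @param pm a `pan_matrix`.
#' @param phenotypes a `phenotype_table` (or compatible character matrix).
#' @param trait column of `phenotypes` to analyse.
#' @param n_trees ensemble size.
#' @param seed RNG seed (forest growth is stochastic).
#' @param importance_threshold report OGs with importance strictly above
#'   this.
#' @param annotation optional named vector OG id -> consensus annotation.
#' @return list of class `gtm_result`: `trait`, `n_pos`, `n_neg`,
#'   `selected` (data.frame `og_id`, `importance`, `pos_fraction`,
#'   `neg_fraction`, `color`, `annotation`, ranked by importance),
#'   `importance` (full named vector incl. zeros for constant OGs).
#' @export
gene_trait_match <- function(pm, phenotypes, trait, n_trees = 1000,
                             seed = 1, importance_threshold = 0.005,
                             annotation = NULL) {
  if (!trait %in% colnames(phenotypes)) {
    stop("unknown trait: ", trait)
  }
  y_raw <- phenotypes[, trait]
  strains <- intersect(colnames(pm$mat), rownames(phenotypes))
  y_raw <- y_raw[strains]
  keep <- y_raw %in% c("growth", "no_growth")
  strains <- strains[keep]
  y <- factor(y_raw[keep], levels = c("no_growth", "growth"))
  if (length(unique(y)) < 2) {
    stop("trait '", trait, "' has a single phenotype class; ",
         "no discriminative signal")
  }
  if (min(table(y)) < 2) {
    stop("trait '", trait, "' needs at least 2 strains per class")
  }
  X <- t(pm$mat[, strains, drop = FALSE])
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  Xv <- X[, !const, drop = FALSE]
  set.seed(seed)
  m <- min(table(y))
  rf <- randomForest::randomForest(
    x = as.data.frame(Xv), y = y, ntree = n_trees,
    strata = y, sampsize = c(m, m))
  imp_raw <- rf$importance[, "MeanDecreaseGini"]
  importance <- setNames(numeric(ncol(X)), colnames(X))
  if (sum(imp_raw) > 0) {
    importance[names(imp_raw)] <- imp_raw / sum(imp_raw)
  }
  sel <- names(importance)[importance > importance_threshold]
  sel <- sel[order(-importance[sel], sel)]
  pos <- strains[y == "growth"]
  neg <- strains[y == "no_growth"]
  pos_frac <- rowMeans(pm$mat[sel, pos, drop = FALSE])
  neg_frac <- rowMeans(pm$mat[sel, neg, drop = FALSE])
  selected <- data.frame(
    og_id = sel,
    importance = unname(importance[sel]),
    pos_fraction = unname(pos_frac),
    neg_fraction = unname(neg_frac),
    color = color_classify(unname(pos_frac)),
    annotation = if (is.null(annotation)) NA_character_ else
      unname(annotation[sel]),
    stringsAsFactors = FALSE)
  rownames(selected) <- NULL
  structure(list(trait = trait, n_pos = length(pos), n_neg = length(neg),
                 selected = selected, importance = importance),
            class = "gtm_result")
}

#' GTM over all traits of a phenotype table
#'
#' Traits with a single class (or too few strains per class) are skipped
#' with a message, mirroring how an automated screen handles
#' uninformative sugars.
#'
#' @param pm a `pan_matrix`.
#' @param phenotypes a `phenotype_table`.
#' @param traits traits to analyse (default: all columns).
#' @param ... passed to [gene_trait_match()].
#' @return named list of `gtm_result` (skipped traits absent).
#' @export
gtm_report <- function(pm, phenotypes, traits = colnames(phenotypes),
                       ...) {
  out <- list()
  for (tr in traits) {
    res <- tryCatch(gene_trait_match(pm, phenotypes, tr, ...),
                    error = function(e) {
                      message("GTM skipped for ", tr, ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) out[[tr]] <- res
  }
  out
}

#' Write a GTM report as TSV (one file per trait) plus an HTML summary
#'
#' The HTML summary mirrors the classic GTM overview layout: one row per
#' selected OG per trait, with importance and the green/red/black colour
#' rendered on the cell.
#'
#' @param report output of [gtm_report()].
#' @param out_dir output directory.
#' @return paths of the files written, invisibly.
#' @export
write_gtm_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  rows <- character(0)
  for (tr in names(report)) {
    res <- report[[tr]]
    p <- file.path(out_dir, paste0("gtm_", tr, ".tsv"))
    write_tsv(res$selected, p)
    paths <- c(paths, p)
    if (nrow(res$selected) > 0) {
      rows <- c(rows, sprintf(
        paste0("<tr><td>%s</td><td>%d</td><td>%d</td><td>%s</td>",
               "<td>%.4f</td><td style=\"color:%s\">%s</td>",
               "<td>%.2f</td><td>%s</td></tr>"),
        tr, res$n_pos, res$n_neg, res$selected$og_id,
        res$selected$importance, res$selected$color, res$selected$color,
        res$selected$pos_fraction,
        ifelse(is.na(res$selected$annotation), "",
               res$selected$annotation)))
    }
  }
  html <- c("<html><head><title>Gene-trait matching</title></head><body>",
            "<h1>Gene-trait matching summary</h1>",
            "<table border=\"1\"><tr><th>trait</th><th>n_pos</th>",
            "<th>n_neg</th><th>OG</th><th>importance</th><th>colour</th>",
            "<th>presence in positive class</th><th>annotation</th></tr>",
            rows, "</table></body></html>")
  hp <- file.path(out_dir, "gtm_summary.html")
  writeLines(html, hp)
  invisible(c(paths, hp))
}
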