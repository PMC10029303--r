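#' Pipeline configuration
#'
#' Collects paths, stage toggles and every tunable of the analysis
#' pipeline. Either `counts_path`/`design_path` or an in-memory
#' [count_matrix()] (passed to [run_pipeline()]) provides the input.
#'
#' @param counts_path,design_path Input TSV paths (optional when a
#'   count matrix is passed directly).
#' @param outdir Output directory for report files; `NULL` disables
#'   file output.
#' @param stages Character vector of stages to run, a subset of
#'   `c("screen", "acde", "plasticity", "network", "associate")`
#'   (contrast estimation always runs).
#' @param acde_quantile Upper-tail fraction for delta-pi selection.
#' @param concordance_null Null proportion of the direction
#'   concordance test.
#' @param bootstrap_reps,bootstrap_threshold Parametric bootstrap
#'   settings.
#' @param evolution_scheme Evolution classification scheme used in the
#'   association tests.
#' @param beta Fixed soft-threshold power (`NULL` = select from
#'   `beta_grid`).
#' @param beta_grid,min_module_size,deep_split Network settings.
#' @param fdr FDR level of the duration screen.
#' @param annotations Optional named list (term -> genes) for
#'   enrichment of the ACDE set.
#' @param hierarchy Optional child-parent term table for level-wise
#'   correction.
#' @param lowland,highland Population codes.
#' @param seed Global seed; each stage derives its own substream so
#'   that toggling stages does not perturb the others.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, design_path = NULL,
                            outdir = NULL,
                            stages = c("screen", "acde", "plasticity",
                                       "network", "associate"),
                            acde_quantile = 0.05,
                            concordance_null = 0.67,
                            bootstrap_reps = 1000,
                            bootstrap_threshold = 950,
                            evolution_scheme = "binary",
                            beta = NULL,
                            beta_grid = seq(2, 30, by = 2),
                            min_module_size = 30, deep_split = 2,
                            fdr = 0.05,
                            annotations = NULL, hierarchy = NULL,
                            lowland = c("L1", "L2"), highland = "H",
                            seed = 1L) {
  stopifnot(acde_quantile > 0, acde_quantile <= 1,
            concordance_null > 0, concordance_null < 1,
            bootstrap_threshold <= bootstrap_reps,
            fdr > 0, fdr < 1)
  unknown <- setdiff(stages, c("screen", "acde", "plasticity",
                               "network", "associate"))
  if (length(unknown)) stop("unknown stage(s): ",
                            paste(unknown, collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(screen = 11L, contrasts = 23L, acde = 37L,
               plasticity = 53L, network = 71L, associate = 89L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full plasticity-evolution pipeline
#'
#' Orchestrates: duration confounder screen, contrast estimation (the
#' two H-vs-lowland contrasts in the high garden, the intra-lowland
#' contrast in the low garden, and the pooled-lowland PC/GC/GC_b
#' contrasts), ACDE selection with the concordance test, plasticity
#' direction/bootstrap/evolution classification plus the continuous
#' interaction magnitude, the signed co-expression network with
#' intramodular connectivity, and the association test battery. When
#' `config$outdir` is set, every result table is written as TSV/JSON
#' along with a manifest recording the seed and configuration.
#'
#' @param config A [pipeline_config()].
#' @param cm Optional [count_matrix()]; when `NULL` the configured
#'   paths are read.
#' @return A list of class `pipeline_result` with elements `excluded`,
#'   `contrasts`, `acde`, `concordance`, `plasticity`, `interaction`,
#'   `network`, `associations`, `enrichment`, `config`.
#' @export
run_pipeline <- function(config, cm = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cm)) {
    if (is.null(config$counts_path) || is.null(config$design_path))
      stop("stage load: no count matrix and no input paths configured")
    cm <- read_counts(config$counts_path, config$design_path)
  }
  res <- list(config = config)
  low <- config$lowland; high <- config$highland

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
  }

  if ("screen" %in% config$stages) {
    res$excluded <- run_stage("screen",
      duration_screen(cm, fdr = config$fdr, lowland = low,
                      highland = high))
    keep <- setdiff(rownames(cm$counts), res$excluded)
    cm <- subset_counts(cm, genes = keep)
  } else res$excluded <- character(0)

  res$contrasts <- run_stage("contrasts", list(
    HL1 = estimate_contrast(cm, select_samples(cm, high, "h"),
                            select_samples(cm, low[1], "h")),
    HL2 = estimate_contrast(cm, select_samples(cm, high, "h"),
                            select_samples(cm, low[2], "h")),
    L1L2 = estimate_contrast(cm, select_samples(cm, low[1], "l"),
                             select_samples(cm, low[2], "l")),
    PC = estimate_contrast(cm, select_samples(cm, low, "h"),
                           select_samples(cm, low, "l")),
    GC = estimate_contrast(cm, select_samples(cm, high, "h"),
                           select_samples(cm, low, "h")),
    GCb = estimate_contrast(cm, select_samples(cm, high, "l"),
                            select_samples(cm, low, "l"))))

  if ("acde" %in% config$stages) {
    res$acde <- run_stage("acde",
      acde_select(res$contrasts$HL1, res$contrasts$HL2,
                  res$contrasts$L1L2, q = config$acde_quantile))
    s <- attr(res$acde, "summary")
    res$concordance <- if (s["n_selected"] > 0)
      concordance_test(s["n_concordant"], s["n_selected"],
                       config$concordance_null) else NULL
    if (!is.null(config$annotations)) {
      res$enrichment <- run_stage("acde", term_enrichment(
        res$acde$gene[res$acde$is_acde], res$acde$gene,
        config$annotations, config$hierarchy))
    }
  }

  if ("plasticity" %in% config$stages) {
    res$plasticity <- run_stage("plasticity", change_table(
      res$contrasts$PC, res$contrasts$GC, res$contrasts$GCb,
      B = config$bootstrap_reps, threshold = config$bootstrap_threshold,
      seed = stage_seed(config, "plasticity")))
    res$interaction <- run_stage("plasticity",
      interaction_magnitude(cm, lowland = low, highland = high))
  }

  if ("network" %in% config$stages) {
    res$network <- run_stage("network", {
      expr <- log_transform(cm)[, select_samples(cm, low), drop = FALSE]
      coexpression_analysis(expr, beta = config$beta,
                            grid = config$beta_grid,
                            min_size = config$min_module_size,
                            deep_split = config$deep_split)
    })
  }

  if ("associate" %in% config$stages &&
      !is.null(res$plasticity)) {
    res$associations <- run_stage("associate",
      association_tests(res, scheme = config$evolution_scheme))
  }

  if (!is.null(config$outdir)) write_reports(res, config$outdir)
  class(res) <- "pipeline_result"
  res
}

evolution_column <- function(scheme) {
  c(binary = "evolution_binary", bin3 = "evolution_bin3",
    bin4 = "evolution_bin4")[[scheme]]
}

# The association battery: each entry is NULL when the fixture lacks
# the categories the test needs (degenerate small inputs).
association_tests <- function(res, scheme = "binary") {
  pl <- res$plasticity
  ecol <- evolution_column(scheme)
  cls <- pl[[ecol]]
  classified <- !cls %in% "unclassified"
  out <- list()

  grp <- split(abs(pl$pc)[classified], cls[classified])
  grp <- grp[vapply(grp, length, 1L) > 0]
  if (length(grp) >= 2)
    out$pc_by_evolution <- kruskal_wallis_dunn(grp)

  dir_ok <- classified & pl$direction != "undefined"
  if (any(dir_ok)) {
    tab <- table(pl$direction[dir_ok], cls[dir_ok])
    if (all(dim(tab) >= 2))
      out$direction_by_evolution <- fisher_exact(tab[1:2, , drop = FALSE])
  }

  if (!is.null(res$network)) {
    conn <- res$network$connectivity
    m <- merge(pl, conn, by = "gene")
    mc <- m[!m[[ecol]] %in% "unclassified" & !is.na(m$k_im), ]
    grp <- split(mc$k_im, mc[[ecol]])
    grp <- grp[vapply(grp, length, 1L) > 0]
    if (length(grp) >= 2) {
      out$kim_by_evolution <- kruskal_wallis_dunn(grp)
      grp_s <- split(mc$k_im_scaled, mc[[ecol]])
      out$kim_scaled_by_evolution <- kruskal_wallis_dunn(grp_s)
    }
    msize <- table(mc$module)
    evolved_frac <- tapply(mc[[ecol]] == "evolved", mc$module, mean)
    if (length(msize) >= 4 && stats::sd(as.numeric(msize)) > 0 &&
        stats::sd(evolved_frac, na.rm = TRUE) > 0)
      out$module_size_vs_evolved <- spearman_one_sided(
        as.numeric(msize), as.numeric(evolved_frac), "less")
  }

  if (!is.null(res$acde)) {
    m <- merge(pl, res$acde[, c("gene", "is_acde")], by = "gene")
    if (length(unique(m$is_acde)) == 2) {
      out$pc_by_acde <- kruskal_wallis_dunn(
        split(abs(m$pc), ifelse(m$is_acde, "acde", "non_acde")))
      if (!is.null(res$interaction)) {
        mi <- merge(m, res$interaction, by = "gene")
        out$evolution_by_acde <- kruskal_wallis_dunn(
          split(mi$magnitude, ifelse(mi$is_acde, "acde", "non_acde")))
      }
      if (!is.null(res$network)) {
        mk <- merge(m, res$network$connectivity, by = "gene")
        mk <- mk[!is.na(mk$k_im), ]
        if (length(unique(mk$is_acde)) == 2)
          out$kim_by_acde <- kruskal_wallis_dunn(
            split(mk$k_im, ifelse(mk$is_acde, "acde", "non_acde")))
      }
    }
  }
  out
}

test_to_row <- function(name, t) {
  data.frame(test = name, statistic = t$statistic, pvalue = t$pvalue)
}

write_reports <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(res$excluded, file.path(outdir, "excluded_genes.txt"))
  for (nm in names(res$contrasts))
    write_tsv(res$contrasts[[nm]],
              file.path(outdir, paste0("contrast_", nm, ".tsv")))
  if (!is.null(res$acde)) write_tsv(res$acde, file.path(outdir, "acde.tsv"))
  if (!is.null(res$plasticity))
    write_tsv(res$plasticity, file.path(outdir, "plasticity.tsv"))
  if (!is.null(res$interaction))
    write_tsv(res$interaction, file.path(outdir, "interaction.tsv"))
  if (!is.null(res$network)) {
    write_tsv(res$network$connectivity,
              file.path(outdir, "connectivity.tsv"))
    jsonlite::write_json(
      list(beta = res$network$beta, r2 = res$network$r2,
           mean_k = res$network$mean_k,
           grid = res$network$beta_table),
      file.path(outdir, "network_diagnostics.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(res$associations)) {
    rows <- do.call(rbind, Map(test_to_row, names(res$associations),
                               res$associations))
    write_tsv(rows, file.path(outdir, "association_tests.tsv"))
  }
  if (!is.null(res$enrichment))
    write_tsv(res$enrichment, file.path(outdir, "enrichment.tsv"))
  cfg <- res$config
  cfg$annotations <- NULL; cfg$hierarchy <- NULL
  manifest <- list(
    package = "plastevo",
    version = as.character(utils::packageVersion("plastevo")),
    r_version = R.version.string,
    seed = res$config$seed,
    config = unclass(cfg),
    config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)),
                                      collapse = ""))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(outdir)
}
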