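#' Assemble a pipeline configuration
#'
#' @param model path to a gene-model file (JSON or GFF3) or \code{"builtin"}
#'   for the packaged TP53 model.
#' @param alignments named character vector mapping sample ids to SAM/BAM
#'   paths.
#' @param annotations path to the sample annotation TSV.
#' @param outdir output directory for stage TSVs and the run manifest.
#' @param params a \code{\link{counting_params}}.
#' @param thresholds a \code{\link{classification_thresholds}}.
#' @param family_alpha,min_group_size,contrasts,fixed_m comparison settings
#'   (see \code{\link{run_comparison_suite}}).
#' @param value fraction column compared ("cterm_fraction" or
#'   "utr5_fraction").
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(model, alignments, annotations, outdir,
                            params = counting_params(),
                            thresholds = classification_thresholds(),
                            family_alpha = 0.05, min_group_size = 5L,
                            contrasts = c("missense", "truncating"),
                            fixed_m = NULL, value = "cterm_fraction") {
  stopifnot(family_alpha > 0, family_alpha <= 1)
  structure(list(model = model, alignments = alignments,
                 annotations = annotations, outdir = outdir,
                 params = params, thresholds = thresholds,
                 family_alpha = family_alpha,
                 min_group_size = as.integer(min_group_size),
                 contrasts = contrasts, fixed_m = fixed_m, value = value),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar keys mirror the arguments of \code{\link{pipeline_config}};
#' \code{alignments} is a mapping of sample id to file path.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    model = y$model,
    alignments = unlist(y$alignments),
    annotations = y$annotations,
    outdir = y$outdir,
    params = do.call(counting_params, as.list(y$params %||% list())),
    thresholds = do.call(classification_thresholds,
                         as.list(y$thresholds %||% list())),
    family_alpha = y$family_alpha %||% 0.05,
    min_group_size = y$min_group_size %||% 5L,
    contrasts = y$contrasts %||% c("missense", "truncating"),
    fixed_m = y$fixed_m,
    value = y$value %||% "cterm_fraction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pre-flight validation of pipeline inputs
#'
#' Reports (never raises) machine-readable findings: missing files,
#' sequence-name disagreement between the gene model and the alignment
#' headers, missing annotation columns, nonsensical thresholds.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return data.frame of findings (stage, finding); zero rows when clean.
#' @export
validate_inputs <- function(config) {
  findings <- NULL
  add <- function(stage, msg)
    rbind(findings, data.frame(stage = stage, finding = msg,
                               stringsAsFactors = FALSE))
  model <- NULL
  if (identical(config$model, "builtin")) {
    model <- builtin_tp53_model()
  } else if (!file.exists(config$model)) {
    findings <- add("model", paste0("model file not found: ", config$model))
  } else {
    model <- tryCatch(load_gene_model(config$model), error = function(e) {
      findings <<- add("model", conditionMessage(e)); NULL
    })
  }
  for (i in seq_along(config$alignments)) {
    f <- config$alignments[i]
    if (!file.exists(f)) {
      findings <- add("alignments", paste0("alignment file not found: ", f))
      next
    }
    if (!is.null(model)) {
      hdr_names <- tryCatch({
        bam <- f
        if (grepl("\\.sam$", f, ignore.case = TRUE))
          bam <- Rsamtools::asBam(f, destination = tempfile(),
                                  overwrite = TRUE, indexDestination = FALSE)
        names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
      }, error = function(e) NULL)
      if (!is.null(hdr_names) && !any(unique(model$chrom) %in% hdr_names))
        findings <- add("alignments",
                        paste0(f, ": no header sequence matches model chrom '",
                               paste(unique(model$chrom), collapse = ","),
                               "' (header: ",
                               paste(utils::head(hdr_names, 5), collapse = ","), ")"))
    }
  }
  if (!file.exists(config$annotations)) {
    findings <- add("annotations",
                    paste0("annotation file not found: ", config$annotations))
  } else {
    tab <- utils::read.delim(config$annotations, nrows = 1)
    need <- c("sample_id", "cohort", "stratum", "mutation_class",
              "log2_cn_ratio", "expression_rsem")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      findings <- add("annotations",
                      paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (config$thresholds$min_expression < 0)
    findings <- add("thresholds", "min_expression is negative")
  if (is.null(findings))
    findings <- data.frame(stage = character(0), finding = character(0))
  findings
}

#' Run the full pipeline: count, fractions, classify, compare
#'
#' Executes the stages in order against the configured inputs, writing one
#' TSV per stage plus a JSON run manifest (config hash, input checksums,
#' per-stage row counts). Any stage failure aborts with a stage-named
#' error; outputs are deterministic given inputs and configuration.
#'
#' @param config a \code{\link{pipeline_config}} or path to a YAML file.
#' @return list: paths of stage outputs, the comparison results, and the
#'   manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  pre <- validate_inputs(config)
  fatal <- pre[pre$stage %in% c("model", "alignments", "annotations") &
               grepl("not found|missing column", pre$finding), ]
  if (nrow(fatal))
    stop("pipeline pre-flight failed:\n  ",
         paste(fatal$stage, fatal$finding, sep = ": ", collapse = "\n  "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  model <- stage("model", if (identical(config$model, "builtin"))
    builtin_tp53_model() else load_gene_model(config$model))
  catalog <- stage("catalog", derive_junctions(model))
  export_junction_catalog(catalog, file.path(config$outdir, "catalog.tsv"))

  counts <- stage("count", lapply(seq_along(config$alignments), function(i)
    count_junction_reads(config$alignments[[i]], catalog,
                         params = config$params,
                         sample_id = names(config$alignments)[i])))
  write_junction_counts(counts, file.path(config$outdir, "counts.tsv"))

  fr <- stage("fractions", fractions_table(counts, catalog))
  write_fractions_table(fr, file.path(config$outdir, "fractions.tsv"))

  ann <- stage("classify", classify_samples(read_annotations(config$annotations),
                                            config$thresholds))
  utils::write.table(ann, file.path(config$outdir, "status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  cmp <- stage("compare", run_comparison_suite(
    fr, ann, value = config$value, contrasts = config$contrasts,
    min_group_size = config$min_group_size,
    family_alpha = config$family_alpha, fixed_m = config$fixed_m))
  utils::write.table(cmp$results, file.path(config$outdir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  cfg_file <- tempfile()
  saveRDS(config[setdiff(names(config), "outdir")], cfg_file)
  inputs <- c(if (!identical(config$model, "builtin")) config$model,
              unname(config$alignments), config$annotations)
  manifest <- list(
    tool_version = as.character(utils::packageVersion("tp53junctions")),
    config_hash = unname(tools::md5sum(cfg_file)),
    input_checksums = as.list(tools::md5sum(inputs)),
    rows = list(catalog = nrow(catalog$junctions), samples = length(counts),
                fractions = nrow(fr), annotations = nrow(ann),
                comparisons = nrow(cmp$results)),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(outdir = config$outdir, catalog = catalog,
                 fractions = fr, comparisons = cmp, manifest = manifest))
}
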