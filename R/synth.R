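# Representative marker/function gene sets for the synthetic cohorts and
# the shipped GMT fixtures. These emulate panel-style immune annotation
# sets; real analyses supply the official sets as GMT input.

cell_type_marker_sets <- function() list(
  T_cells          = c("CD3D", "CD3E", "CD3G", "CD6", "SH2D1A", "TRAT1"),
  CD8_T_cells      = c("CD8A", "CD8B"),
  Cytotoxic_cells  = c("GZMA", "GZMB", "GZMH", "PRF1", "KLRK1", "NKG7"),
  B_cells          = c("CD19", "MS4A1", "CD79A", "CD79B", "BLK"),
  CD45_cells       = c("PTPRC", "LAPTM5"),
  Macrophages      = c("CD68", "CD163", "CD84", "MS4A4A"),
  Exhausted_CD8    = c("CD244", "EOMES", "PTGER4"),
  Th1_cells        = c("TBX21", "STAT4", "IL12RB2"),
  NK_cells         = c("NCR1", "KIR2DL3", "XCL2", "NCAM1"),
  Dendritic_cells  = c("ITGAX", "CD1C", "CLEC4C", "NRP1"),
  Treg             = c("FOXP3", "IKZF2"),
  Mast_cells       = c("TPSAB1", "TPSB2", "CPA3", "MS4A2"),
  Neutrophils      = c("FCGR3B", "CSF3R", "S100A12", "CEACAM3"))

functional_signature_sets <- function() list(
  T_cell_function     = c("ICOS", "CD28", "CD40LG", "IL2RB", "ZAP70",
                          "LCK", "ITK", "CD27"),
  NK_cell_function    = c("KLRC1", "KLRD1", "KLRF1", "NCR3", "FASLG",
                          "SH2D1B"),
  B_cell_function     = c("CD40", "TNFRSF13B", "TNFRSF13C", "PAX5",
                          "BLNK", "FCRL2"),
  Macrophage_function = c("MARCO", "MSR1", "MRC1", "CD86", "TLR4", "NOS2"),
  Leukocyte_function  = c("ITGAL", "ITGB2", "SELL", "CD2", "CD5", "PTPN22"),
  Cytokines           = c("IFNG", "TNF", "IL15", "IL21", "CSF2", "LTA"),
  Chemokines          = c("CXCL9", "CXCL10", "CXCL11", "CCL5", "CCL4",
                          "CXCL13", "CCR5"),
  Interleukins        = c("IL2", "IL4", "IL6", "IL7", "IL10", "IL1B",
                          "IL18"),
  Complement          = c("C1QA", "C1QB", "C2", "C3", "C7", "CFB",
                          "C5AR1"))

#' Checkpoint / immunomodulatory genes tracked across the four classes
#' @export
checkpoint_genes <- function()
  c("PDCD1", "CD274", "CTLA4", "HAVCR2", "IDO1", "LAG3", "TIGIT",
    "TNFRSF4", "BTK", "TGFB1")

#' Housekeeping genes used for panel-style normalisation
#' @export
housekeeping_genes <- function()
  c("ACTB", "GAPDH", "TUBB", "TBP", "POLR2A", "RPLP0", "SDHA", "UBC")

# genes carrying planted survival hazards (kept outside the signature sets
# so survival screening can be validated independently of classification)
hazard_gene_defaults <- function()
  c(HLA_DQA1 = 1.0, DUSP4 = -1.0, IRF4 = -1.0, CCRL2 = -1.0)

#' Default signature collection of the synthetic cohorts
#'
#' Cell-type marker sets, functional signature sets, and an ESTIMATE-style
#' immune gene set (the union of all immune marker and function genes).
#' @return a `SignatureCollection`.
#' @export
default_signatures <- function() {
  cell <- cell_type_marker_sets()
  fun <- functional_signature_sets()
  sigs <- c(
    lapply(names(cell), function(n) gene_signature(n, "cell_type", cell[[n]])),
    lapply(names(fun), function(n) gene_signature(n, "function", fun[[n]])),
    list(gene_signature("Immune_estimate", "immune_estimate",
                        unique(c(unlist(cell), unlist(fun))))))
  signature_collection(sigs)
}

#' Specification of a synthetic cohort
#'
#' Encodes the data-generating assumptions the analysis targets: two
#' infiltrate strata differing in cell-type marker expression, two function
#' strata differing in functional-signature expression, extra checkpoint /
#' immunomodulatory elevation and CDH1 reduction in IIH-FH, higher plasma
#' IL-18 in FH, gene-tied survival hazards, and a response probability
#' increasing with CPS and IIH-FH membership. All cohorts are CPS < 5 by
#' design (CPS drawn from 0..4).
#'
#' @param n_samples cohort size (>= 8), default 60.
#' @param n_genes genes in the matrix (>= 200), default 2000.
#' @param class_proportions length-4 proportions over
#'   IIL-FL, IIL-FH, IIH-FL, IIH-FH (sum 1), default
#'   c(0.35, 0.10, 0.30, 0.25).
#' @param infiltrate_effect log2 shift of cell-type marker genes in IIH,
#'   default 2.0.
#' @param function_effect log2 shift of functional-signature genes in FH,
#'   default 1.5.
#' @param checkpoint_effect extra log2 shift of checkpoint genes in IIH-FH,
#'   default 1.0.
#' @param cdh1_effect (negative) CDH1 log2 shift in IIH-FH, default -1.5.
#' @param il18_effect plasma IL-18 mean shift (pg/mL) in FH, default 120.
#' @param noise_sd residual log2 SD, default 1.
#' @param hazard_betas named log-hazard coefficients per standardised gene
#'   expression; default +1 HLA_DQA1, -1 DUSP4/IRF4/CCRL2.
#' @param censoring_rate target fraction censored in [0, 1), default 0.3.
#' @param response_model c(intercept, cps_coef, iihfh_coef) of the logistic
#'   response model, default c(-2.5, 0.3, 2.5): about 27% responders overall with roughly two thirds of them in IIH-FH, matching a CPI-exposed validation design.
#' @param seed integer seed.
#' @return a `SyntheticCohortSpec` list.
#' @export
cohort_spec <- function(n_samples = 60, n_genes = 2000,
                        class_proportions = c(0.35, 0.10, 0.30, 0.25),
                        infiltrate_effect = 2.0, function_effect = 1.5,
                        checkpoint_effect = 1.0, cdh1_effect = -1.5,
                        il18_effect = 120, noise_sd = 1,
                        hazard_betas = hazard_gene_defaults(),
                        censoring_rate = 0.3,
                        response_model = c(-2.5, 0.3, 2.5), seed = 1) {
  stopifnot(length(class_proportions) == 4)
  if (abs(sum(class_proportions) - 1) > 1e-12)
    stop_ic("class proportions must sum to 1")
  if (noise_sd <= 0) stop_ic("noise_sd must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop_ic("censoring_rate must lie in [0, 1)")
  if (cdh1_effect > 0) stop_ic("cdh1_effect must be <= 0")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 class_proportions = class_proportions,
                 infiltrate_effect = infiltrate_effect,
                 function_effect = function_effect,
                 checkpoint_effect = checkpoint_effect,
                 cdh1_effect = cdh1_effect, il18_effect = il18_effect,
                 noise_sd = noise_sd, hazard_betas = hazard_betas,
                 censoring_rate = censoring_rate,
                 response_model = response_model, seed = seed),
            class = "SyntheticCohortSpec")
}

# largest-remainder rounding of class counts
class_counts_from_proportions <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Baseline log2 expression is Gaussian (gene means ~ Normal(5, 1.5),
#' residual SD `noise_sd`); class-tied shifts are added per the planted
#' truth class of each sample;
#' PFS times are exponential with log-hazard equal to the weighted sum of
#' standardised hazard-gene expression, censored by an independent
#' exponential calibrated to `censoring_rate`; response is Bernoulli on the
#' logistic scale in CPS and IIH-FH membership; plasma IL-18 is Gaussian
#' with an FH mean shift. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param mode `"log2norm"` (default) or `"counts"` (negative-binomial
#'   counts with gene-level dispersion 0.2 around 2^log2-mean, with
#'   per-sample library factors; used to exercise
#'   [normalize_housekeeping()]).
#' @return a `SyntheticCohort` list: `expr` (`ExpressionMatrix`),
#'   `annotations` (data.frame), `truth` (data.frame sample_id /
#'   infiltrate / function / combined), `signatures`
#'   (`SignatureCollection` incl. planted hallmark sets),
#'   `housekeeping`, `spec`.
#' @export
generate_cohort <- function(spec, mode = c("log2norm", "counts")) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  mode <- match.arg(mode)
  if (spec$n_samples < 8) stop_ic("n_samples must be >= 8")
  if (spec$n_genes < 200) stop_ic("n_genes must be >= 200")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  cell <- cell_type_marker_sets(); fun <- functional_signature_sets()
  cell_genes <- unique(unlist(cell))
  fun_genes <- unique(unlist(fun))
  named <- unique(c(cell_genes, fun_genes, checkpoint_genes(), "CDH1",
                    names(hazard_gene_defaults()), names(spec$hazard_betas),
                    housekeeping_genes()))
  n_fill <- spec$n_genes - length(named)
  if (n_fill < 0) stop_ic("n_genes too small for the named gene sets")
  genes <- c(named, sprintf("GENE%04d", seq_len(n_fill)))
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))

  lev <- c("IIL-FL", "IIL-FH", "IIH-FL", "IIH-FH")
  counts <- class_counts_from_proportions(n, spec$class_proportions)
  combined <- sample(rep(lev, counts))
  infiltrate <- ifelse(combined %in% c("IIH-FL", "IIH-FH"), "IIH", "IIL")
  fun_lab <- ifelse(combined %in% c("IIL-FH", "IIH-FH"), "FH", "FL")

  mu <- stats::rnorm(length(genes), 5, 1.5)
  names(mu) <- genes
  mu[housekeeping_genes()] <- 8          # housekeeping: high, class-free
  vals <- matrix(stats::rnorm(length(genes) * n, 0, spec$noise_sd),
                 nrow = length(genes),
                 dimnames = list(genes, samples)) + mu
  iih <- infiltrate == "IIH"; fh <- fun_lab == "FH"; iihfh <- combined == "IIH-FH"
  vals[cell_genes, iih] <- vals[cell_genes, iih] + spec$infiltrate_effect
  vals[fun_genes, fh] <- vals[fun_genes, fh] + spec$function_effect
  vals[checkpoint_genes(), iihfh] <-
    vals[checkpoint_genes(), iihfh] + spec$checkpoint_effect
  vals["CDH1", iihfh] <- vals["CDH1", iihfh] + spec$cdh1_effect

  # survival tied to the hazard genes via standardised expression
  hz <- spec$hazard_betas
  hz <- hz[names(hz) %in% genes]
  lp <- if (length(hz) > 0) {
    z <- scale(t(vals[names(hz), , drop = FALSE]))
    as.numeric(z %*% hz)
  } else rep(0, n)
  base_rate <- log(2) / 8                 # median PFS ~8 months at lp = 0
  rate <- base_rate * exp(lp)
  t_event <- stats::rexp(n, rate)
  if (spec$censoring_rate > 0) {
    f <- function(cr) mean(cr / (cr + rate)) - spec$censoring_rate
    cr <- stats::uniroot(f, c(1e-8, 1e4))$root
    t_cens <- stats::rexp(n, cr)
  } else t_cens <- rep(Inf, n)
  pfs_time <- pmin(t_event, t_cens)
  pfs_event <- as.integer(t_event <= t_cens)

  cps <- sample(0:4, n, replace = TRUE)
  rm_ <- spec$response_model
  p_resp <- stats::plogis(rm_[1] + rm_[2] * cps + rm_[3] * iihfh)
  resp <- stats::rbinom(n, 1, p_resp)
  il18 <- pmax(0, stats::rnorm(n, 300, 80) + spec$il18_effect * fh)
  subtype <- sample(c("CIN", "GS", "EBV", "MSI"), n, replace = TRUE,
                    prob = c(0.55, 0.25, 0.08, 0.12))

  if (mode == "counts") {
    libf <- 2^stats::rnorm(n, 0, 0.4)
    mu_counts <- sweep(2^vals, 2, libf, `*`)
    cnt <- matrix(stats::rnbinom(length(mu_counts), mu = mu_counts,
                                 size = 1 / 0.2),
                  nrow = nrow(mu_counts), dimnames = dimnames(vals))
    expr <- expression_matrix(cnt, scale = "counts")
  } else {
    expr <- expression_matrix(vals, scale = "log2norm")
  }

  ann <- data.frame(sample_id = samples, cps = cps, subtype = subtype,
                    pfs_time = pfs_time, pfs_event = pfs_event,
                    response = ifelse(resp == 1, "responder",
                                      "non_responder"),
                    batch = "batch1", il18 = il18,
                    platinum_exposed = TRUE, stringsAsFactors = FALSE)

  truth <- data.frame(sample_id = samples, infiltrate = infiltrate,
                      `function` = fun_lab, combined = combined,
                      check.names = FALSE, stringsAsFactors = FALSE)

  # planted hallmark-style sets: immune ones drawn from the shifted genes,
  # proliferation-style ones from unshifted filler genes
  fill <- genes[startsWith(genes, "GENE")]
  immune_pool <- unique(c(fun_genes, cell_genes))
  hm <- list(
    HM_INFLAMMATORY_RESPONSE = sample(immune_pool, 15),
    HM_IFN_GAMMA_RESPONSE = sample(immune_pool, 15),
    HM_IL2_STAT5_SIGNALING = sample(immune_pool, 15),
    HM_EMT = c("CDH1", "TGFB1", sample(fill, 13)),
    HM_E2F_TARGETS = sample(fill, 15),
    HM_MYC_TARGETS = sample(fill, 15),
    HM_G2M_CHECKPOINT = sample(fill, 15))
  sigs <- default_signatures()
  sigs <- signature_collection(c(sigs$signatures,
                                 lapply(names(hm), function(nn)
                                   gene_signature(nn, "hallmark", hm[[nn]]))))

  structure(list(expr = expr, annotations = ann, truth = truth,
                 signatures = sigs, housekeeping = housekeeping_genes(),
                 spec = spec),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d genes x %d samples; classes: %s\n",
              nrow(x$expr$values), ncol(x$expr$values),
              paste(names(table(x$truth$combined)),
                    table(x$truth$combined), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic CPI-exposed validation cohort
#'
#' As [generate_cohort()], but sized and structured like an external
#' checkpoint-inhibitor-treated validation cohort: 45 patients by default,
#' no IIL-FH stratum (three observed classes), and guaranteed to contain at
#' least one responder and one non-responder (the response draw is repeated
#' with fresh randomness, deterministically under the seed, if degenerate).
#'
#' @param spec a [cohort_spec()]; `n_samples` and `class_proportions` are
#'   overridden by `n` and `class_proportions`.
#' @param n cohort size, default 45.
#' @param class_proportions default c(0.40, 0, 0.35, 0.25).
#' @return a `SyntheticCohort`.
#' @export
generate_external_cohort <- function(spec, n = 45,
                                     class_proportions =
                                       c(0.40, 0, 0.35, 0.25)) {
  spec$n_samples <- n
  spec$class_proportions <- class_proportions
  cohort <- generate_cohort(spec)
  tries <- 0
  while (length(unique(cohort$annotations$response)) < 2 && tries < 100) {
    tries <- tries + 1
    spec2 <- spec; spec2$seed <- derive_seed(spec$seed, 7919 + tries)
    cohort <- generate_cohort(spec2)
  }
  if (length(unique(cohort$annotations$response)) < 2)
    stop_ic("could not generate both responders and non-responders")
  cohort
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the expression TSV, planted signature GMT, annotation TSV, truth
#' TSV, and the spec as YAML into a directory.
#'
#' @param cohort a `SyntheticCohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_table(cohort$expr, file.path(dir, "expression.tsv"))
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  utils::write.table(cohort$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- cohort$spec
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.yaml"))
  invisible(dir)
}
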