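#' @keywords internal
#' @importFrom stats rnorm qt pt pf lm deviance setNames
"_PACKAGE"

# genotype group labels used throughout (long-format `group` column)
.groups <- c(gmo = "gmo", comparator = "comparator", reference = "reference")

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

#' Build a balanced multi-site RCBD trial design
#'
#' Constructs the standard layout for a GM compositional field trial: one GM
#' test entry, its conventional comparator and a set of commercial reference
#' varieties, every genotype grown once per block, blocks nested within sites,
#' the full genotype roster present at every site (a complete, balanced
#' design).
#'
#' @param n_sites Number of sites (\eqn{\ge 2}).
#' @param n_blocks Number of blocks per site (\eqn{\ge 2}).
#' @param n_reference Number of reference varieties (\eqn{\ge 1}).
#' @return An object of class `trial_design`: a list with `n_sites`,
#'   `n_blocks`, a `genotypes` data frame (`label`, `group`) and `balanced`
#'   (always `TRUE`).
#' @examples
#' build_design(4, 4, 6)   # the 128-plot default layout
#' @export
build_design <- function(n_sites, n_blocks, n_reference) {
  if (!.is_count(n_sites) || n_sites < 2)
    stop("`n_sites` must be an integer >= 2 (got ", deparse(n_sites), ")", call. = FALSE)
  if (!.is_count(n_blocks) || n_blocks < 2)
    stop("`n_blocks` must be an integer >= 2 (got ", deparse(n_blocks), ")", call. = FALSE)
  if (!.is_count(n_reference) || n_reference < 1)
    stop("`n_reference` must be an integer >= 1 (got ", deparse(n_reference), ")", call. = FALSE)
  genotypes <- data.frame(
    label = c("GMO", "Comparator", sprintf("Ref%02d", seq_len(n_reference))),
    group = c(.groups[["gmo"]], .groups[["comparator"]],
              rep(.groups[["reference"]], n_reference)),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_sites = as.integer(n_sites), n_blocks = as.integer(n_blocks),
         genotypes = genotypes, balanced = TRUE),
    class = "trial_design"
  )
}

n_genotypes <- function(design) nrow(design$genotypes)
n_reference <- function(design) sum(design$group_vec == "reference")

# convenience accessors used all over the package
.design_dims <- function(design) {
  g <- nrow(design$genotypes)
  list(s = design$n_sites, b = design$n_blocks, g = g,
       r = sum(design$genotypes$group == "reference"),
       N = design$n_sites * design$n_blocks * g,
       ref_idx = which(design$genotypes$group == "reference"),
       gmo_idx = which(design$genotypes$group == "gmo"),
       comp_idx = which(design$genotypes$group == "comparator"))
}

#' Number of plots in a design
#' @param design A `trial_design`.
#' @return Integer plot count (sites x blocks x genotypes).
#' @export
n_plots <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  design$n_sites * design$n_blocks * nrow(design$genotypes)
}

#' @export
print.trial_design <- function(x, ...) {
  d <- .design_dims(x)
  cat("Balanced multi-site RCBD trial design\n")
  cat(sprintf("  sites: %d, blocks/site: %d, genotypes: %d (1 GMO, 1 comparator, %d reference)\n",
              d$s, d$b, d$g, d$r))
  cat(sprintf("  plots: %d\n", d$N))
  invisible(x)
}

#' Random-effect variance components of the trial model
#'
#' All variances are on the (log) response scale. The site-by-genotype
#' interaction can be given either as a single pooled component
#' (`interaction`) or partitioned into a site-by-test-entry component
#' (`interaction_test`, covering the GMO and comparator cells) and a
#' site-by-reference-variety component (`interaction_reference`). The two
#' parameterizations are mutually exclusive.
#'
#' @param site Between-site variance.
#' @param block Between-block-within-site variance.
#' @param genotype Variance among reference varieties (the reference
#'   population's genetic variance, V_g).
#' @param interaction Pooled site-by-genotype interaction variance.
#' @param interaction_test,interaction_reference Optional partitioned
#'   interaction variances; supply both or neither.
#' @param residual Plot error variance.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(site = 0.02, block = 0.005, genotype = 0.01,
                                interaction = 0, interaction_test = NULL,
                                interaction_reference = NULL, residual = 0.01) {
  partitioned <- !is.null(interaction_test) || !is.null(interaction_reference)
  if (partitioned && (is.null(interaction_test) || is.null(interaction_reference)))
    stop("supply both `interaction_test` and `interaction_reference`, or neither",
         call. = FALSE)
  if (partitioned && !missing(interaction) && !is.null(interaction))
    stop("inconsistent configuration: pooled `interaction` and partitioned ",
         "interaction components are mutually exclusive", call. = FALSE)
  vals <- c(site = site, block = block, genotype = genotype,
            interaction = if (partitioned) NA_real_ else interaction,
            interaction_test = if (partitioned) interaction_test else NA_real_,
            interaction_reference = if (partitioned) interaction_reference else NA_real_,
            residual = residual)
  chk <- vals[!is.na(vals)]
  if (any(!is.finite(chk)) || any(chk < 0))
    stop("all variance components must be finite and >= 0", call. = FALSE)
  structure(list(site = site, block = block, genotype = genotype,
                 interaction = if (partitioned) NA_real_ else interaction,
                 interaction_test = if (partitioned) interaction_test else NA_real_,
                 interaction_reference = if (partitioned) interaction_reference else NA_real_,
                 residual = residual, partitioned = partitioned),
            class = "variance_components")
}

# interaction sd per genotype row (length g), for the simulator
.interaction_sds <- function(vc, dims) {
  sds <- numeric(dims$g)
  if (vc$partitioned) {
    sds[c(dims$gmo_idx, dims$comp_idx)] <- sqrt(vc$interaction_test)
    sds[dims$ref_idx] <- sqrt(vc$interaction_reference)
  } else {
    sds[] <- sqrt(vc$interaction)
  }
  sds
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (log scale)\n")
  cat(sprintf("  site: %g  block(site): %g  genotype (V_g): %g  residual: %g\n",
              x$site, x$block, x$genotype, x$residual))
  if (x$partitioned)
    cat(sprintf("  site x test-entry: %g  site x reference: %g (partitioned)\n",
                x$interaction_test, x$interaction_reference))
  else
    cat(sprintf("  site x genotype (pooled): %g\n", x$interaction))
  invisible(x)
}

#' Fixed mean structure of the trial model
#'
#' @param overall Grand mean on the log scale.
#' @param gmo_offset Fixed offset of the GM entry (the simulation parameter
#'   usually written mu_GMO).
#' @param comparator_offset Fixed offset of the comparator.
#' @param reference_mode `"random"` (reference variety effects drawn from a
#'   zero-mean normal with variance `genotype`) or `"fixed"` (explicit
#'   per-variety offsets in `reference_offsets`).
#' @param reference_offsets Numeric vector of per-reference-variety offsets,
#'   only under `reference_mode = "fixed"`.
#' @return An object of class `mean_structure`.
#' @export
mean_structure <- function(overall = 0, gmo_offset = 0, comparator_offset = 0,
                           reference_mode = c("random", "fixed"),
                           reference_offsets = NULL) {
  reference_mode <- match.arg(reference_mode)
  if (reference_mode == "random" && !is.null(reference_offsets))
    stop("explicit `reference_offsets` are not allowed under reference_mode = \"random\"",
         call. = FALSE)
  if (reference_mode == "fixed" && is.null(reference_offsets))
    stop("reference_mode = \"fixed\" requires `reference_offsets`", call. = FALSE)
  stopifnot(is.finite(overall), is.finite(gmo_offset), is.finite(comparator_offset))
  structure(list(overall = overall, gmo_offset = gmo_offset,
                 comparator_offset = comparator_offset,
                 reference_mode = reference_mode,
                 reference_offsets = reference_offsets),
            class = "mean_structure")
}

#' Assemble a plot-level trial dataset
#'
#' Wraps a long-format data frame (one row per plot) as a `trial_dataset`,
#' attaching the design it conforms to. Columns: `site`, `block`, `genotype`,
#' `group`, `response` (log scale).
#'
#' @param records Data frame with the five schema columns.
#' @param design The `trial_design` the records conform to; reconstructed from
#'   the records when omitted.
#' @param validate Run [validate_dataset()] and fail on problems (default TRUE).
#' @return A `trial_dataset` (a data frame with a `design` attribute).
#' @export
trial_dataset <- function(records, design = NULL, validate = TRUE) {
  needed <- c("site", "block", "genotype", "group", "response")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  records <- as.data.frame(records)[, needed]
  bad_grp <- !records$group %in% .groups
  if (any(bad_grp))
    stop("unknown group label(s): ", paste(unique(records$group[bad_grp]), collapse = ", "),
         call. = FALSE)
  if (is.null(design)) design <- .design_from_records(records)
  out <- structure(records, class = c("trial_dataset", "data.frame"),
                   design = design)
  if (validate) {
    rep <- validate_dataset(out)
    if (!rep$ok)
      stop("invalid trial dataset:\n", paste(format(rep), collapse = "\n"), call. = FALSE)
  }
  out
}

# infer the design implied by a long-format table (used by the CSV reader)
.design_from_records <- function(records) {
  sites <- sort(unique(records$site))
  blocks <- sort(unique(records$block))
  gmap <- unique(records[, c("genotype", "group")])
  if (anyDuplicated(gmap$genotype))
    stop("genotype label(s) mapped to more than one group: ",
         paste(unique(gmap$genotype[duplicated(gmap$genotype)]), collapse = ", "),
         call. = FALSE)
  ord <- order(match(gmap$group, .groups), gmap$genotype)
  gmap <- gmap[ord, , drop = FALSE]
  if (sum(gmap$group == "gmo") != 1L || sum(gmap$group == "comparator") != 1L ||
      sum(gmap$group == "reference") < 1L)
    stop("a trial needs exactly one gmo, exactly one comparator and at least one ",
         "reference variety; found ", sum(gmap$group == "gmo"), " gmo, ",
         sum(gmap$group == "comparator"), " comparator, ",
         sum(gmap$group == "reference"), " reference", call. = FALSE)
  if (length(sites) < 2 || length(blocks) < 2)
    stop("a trial needs at least 2 sites and 2 blocks per site", call. = FALSE)
  structure(list(n_sites = length(sites), n_blocks = length(blocks),
                 genotypes = data.frame(label = gmap$genotype, group = gmap$group,
                                        stringsAsFactors = FALSE),
                 balanced = TRUE, site_levels = sites, block_levels = blocks),
            class = "trial_design")
}

#' Validate a trial dataset against its design
#'
#' Report-style check of the dataset invariants: exactly one record per
#' (site, block, genotype) cell and finite responses. Problems are listed,
#' never thrown.
#'
#' @param data A `trial_dataset` (or plain data frame with the schema columns).
#' @param design The design to check against; defaults to the dataset's own.
#' @return A `trial_validation` list: `ok` flag plus data frames `missing`,
#'   `duplicated` and `non_finite`.
#' @export
validate_dataset <- function(data, design = attr(data, "design")) {
  if (is.null(design)) design <- .design_from_records(data)
  sites <- if (!is.null(design$site_levels)) design$site_levels else seq_len(design$n_sites)
  blocks <- if (!is.null(design$block_levels)) design$block_levels else seq_len(design$n_blocks)
  expected <- expand.grid(genotype = design$genotypes$label, block = blocks,
                          site = sites, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  key <- function(d) paste(d$site, d$block, d$genotype, sep = "\r")
  obs <- key(data)
  exp_key <- key(expected)
  missing <- expected[!exp_key %in% obs, c("site", "block", "genotype")]
  dup <- unique(data[obs %in% obs[duplicated(obs)], c("site", "block", "genotype")])
  stray <- data[!obs %in% exp_key, c("site", "block", "genotype")]
  nf <- data[!is.finite(data$response), c("site", "block", "genotype", "response")]
  ok <- nrow(missing) == 0 && nrow(dup) == 0 && nrow(nf) == 0 && nrow(stray) == 0
  structure(list(ok = ok, missing = missing, duplicated = dup, stray = stray,
                 non_finite = nf),
            class = "trial_validation")
}

#' @export
format.trial_validation <- function(x, ...) {
  if (x$ok) return("dataset is complete, balanced and finite")
  line <- function(df, what)
    if (nrow(df)) sprintf("%s cell(s): %s", what,
                          paste(apply(df[, 1:3], 1, paste, collapse = "/"), collapse = ", "))
  c(Filter(Negate(is.null),
           list(line(x$missing, "missing"), line(x$duplicated, "duplicated"),
                line(x$stray, "unexpected"),
                if (nrow(x$non_finite)) sprintf("non-finite response in cell(s): %s",
                  paste(apply(x$non_finite[, 1:3], 1, paste, collapse = "/"), collapse = ", ")))))
}

#' @export
print.trial_validation <- function(x, ...) {
  cat(paste(format(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- .design_dims(attr(x, "design"))
  cat(sprintf("Trial dataset: %d plots (%d sites x %d blocks x %d genotypes)\n",
              nrow(x), d$s, d$b, d$g))
  if (!is.null(attr(x, "seed"))) cat(sprintf("  simulated with seed %d\n", attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
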