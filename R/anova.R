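# ---- stratum arithmetic ----------------------------------------------------
#
# All decomposition work happens on a response vector in canonical order
# (genotype fastest, then block, then site). Balanced complete data only, so
# every stratum SS is a closed-form function of cell means and the strata are
# mutually orthogonal; no iterative fitting anywhere.

.strata_names <- c("site", "block_in_site", "genotype_group",
                   "genotype_within_reference", "site_x_test",
                   "site_x_reference", "site_x_group", "residual")

.strata_df <- function(d) {
  c(site = d$s - 1L,
    block_in_site = d$s * (d$b - 1L),
    genotype_group = 2L,
    genotype_within_reference = d$r - 1L,
    site_x_test = d$s - 1L,
    site_x_reference = (d$s - 1L) * (d$r - 1L),
    site_x_group = d$s - 1L,
    residual = d$s * (d$b - 1L) * (d$g - 1L))
}

# stratum sums of squares for one canonical-order response vector
.strata_ss <- function(y, d) {
  s <- d$s; b <- d$b; g <- d$g; r <- d$r
  Ym <- matrix(y, g, b * s)                       # columns = (block, site) cells
  m_bs <- colMeans(Ym)                            # block-within-site means
  m_s <- colMeans(matrix(m_bs, b, s))             # site means
  site_col <- rep(seq_len(s), each = b)
  m_gs <- Ym %*% (diag(s)[site_col, , drop = FALSE] / b)  # genotype x site cell means
  m_g <- rowMeans(m_gs)                           # genotype means
  grand <- mean(m_s)

  ss_site <- b * g * sum((m_s - grand)^2)
  ss_block <- g * sum((m_bs - m_s[site_col])^2)

  m_ref <- mean(m_g[d$ref_idx])
  ss_group <- s * b * ((m_g[d$gmo_idx] - grand)^2 + (m_g[d$comp_idx] - grand)^2 +
                         r * (m_ref - grand)^2)
  ss_genref <- s * b * sum((m_g[d$ref_idx] - m_ref)^2)

  int_dev <- m_gs - rep(m_s, each = g)            # recycle: subtract site means
  int_dev <- int_dev - m_g + grand                # and genotype means
  ss_int <- b * sum(int_dev^2)
  dvec <- m_gs[d$gmo_idx, ] - m_gs[d$comp_idx, ]
  ss_sxt <- b * sum((dvec - mean(dvec))^2) / 2
  if (r >= 2) {
    A <- m_gs[d$ref_idx, , drop = FALSE]          # reference cells only
    A <- sweep(A, 1, rowMeans(A))                 # double-center: rows, then
    A <- sweep(A, 2, colMeans(A))                 # columns of the row-centered
    ss_sxr <- b * sum(A^2)
  } else ss_sxr <- 0
  ss_sxg <- ss_int - ss_sxt - ss_sxr
  if (ss_sxg < 0) ss_sxg <- max(ss_sxg, 0)        # guard fp dust at exact zero

  resid <- Ym - rep(m_bs, each = g) - m_gs[, site_col] + rep(m_s[site_col], each = g)
  ss_resid <- sum(resid^2)

  c(site = ss_site, block_in_site = ss_block, genotype_group = ss_group,
    genotype_within_reference = ss_genref, site_x_test = ss_sxt,
    site_x_reference = ss_sxr, site_x_group = ss_sxg, residual = ss_resid)
}

# reorder a dataset's response into canonical order against its design
.canonical_y <- function(data, design) {
  d <- .design_dims(design)
  if (isTRUE(attr(data, "canonical")) && nrow(data) == d$N)
    return(list(y = data$response, d = d))
  rep <- validate_dataset(data, design)
  if (!rep$ok)
    stop("unbalanced or incomplete dataset: the closed-form decomposition needs a ",
         "complete balanced trial (", paste(format(rep), collapse = "; "),
         "). For unbalanced data fit a mixed model by REML instead (see the ",
         "package vignette).", call. = FALSE)
  sites <- if (!is.null(design$site_levels)) design$site_levels else seq_len(d$s)
  blocks <- if (!is.null(design$block_levels)) design$block_levels else seq_len(d$b)
  si <- match(data$site, sites)
  bi <- match(data$block, blocks)
  gi <- match(data$genotype, design$genotypes$label)
  ord <- order(si, bi, gi)
  list(y = data$response[ord], d = d)
}

#' Balanced ANOVA decomposition of a trial dataset
#'
#' Classical sums-of-squares decomposition of the trial model for a complete
#' balanced multi-site RCBD, with the genotype stratum split into group
#' contrasts (GMO / comparator / reference population) and
#' genotype-within-reference, and the site-by-genotype interaction split into
#' site-by-test-entry (the GMO-vs-comparator contrast by site),
#' site-by-reference-variety, and the remaining site-by-group contrast.
#' Purely arithmetic; strata are orthogonal, so stratum SS sum exactly to the
#' total SS.
#'
#' @param data A complete balanced `trial_dataset`.
#' @param design Its design (defaults to the attached one).
#' @return A `trial_anova`: data frame with columns `stratum`, `df`, `ss`,
#'   `ms`, plus attributes `total_ss`, `total_df` and the design.
#' @export
decompose_trial <- function(data, design = attr(data, "design")) {
  if (is.null(design)) design <- .design_from_records(data)
  cy <- .canonical_y(data, design)
  ss <- .strata_ss(cy$y, cy$d)
  df <- .strata_df(cy$d)
  out <- data.frame(stratum = .strata_names, df = as.integer(df[.strata_names]),
                    ss = ss[.strata_names], row.names = NULL,
                    stringsAsFactors = FALSE)
  out$ms <- ifelse(out$df > 0, out$ss / out$df, NA_real_)
  structure(out, class = c("trial_anova", "data.frame"),
            total_ss = sum((cy$y - mean(cy$y))^2), total_df = cy$d$N - 1L,
            design = design)
}

#' @export
print.trial_anova <- function(x, ...) {
  cat("Balanced trial ANOVA decomposition\n")
  print.data.frame(cbind(as.data.frame(x)[1:2],
                         round(as.data.frame(x)[3:4], 6)), row.names = FALSE)
  cat(sprintf("total SS %.6g on %d df\n", attr(x, "total_ss"), attr(x, "total_df")))
  invisible(x)
}

.anova_get <- function(decomp, stratum, col = "ms") {
  decomp[[col]][match(stratum, decomp$stratum)]
}

# pooled site-by-genotype interaction (all three interaction strata together)
.pooled_interaction <- function(decomp) {
  rows <- decomp$stratum %in% c("site_x_test", "site_x_reference", "site_x_group")
  list(ss = sum(decomp$ss[rows]), df = sum(decomp$df[rows]),
       ms = sum(decomp$ss[rows]) / sum(decomp$df[rows]))
}

# pooled error of the no-interaction model: interaction SS folded into residual
.pooled_error <- function(decomp) {
  int <- .pooled_interaction(decomp)
  ss <- int$ss + .anova_get(decomp, "residual", "ss")
  df <- int$df + .anova_get(decomp, "residual", "df")
  list(ss = ss, df = df, ms = ss / df)
}

# ---- expected mean squares -------------------------------------------------

# E[SS_stratum] coefficient of one variance component = tr(A Z Z') where A is
# the stratum quadratic form; computed exactly as sum over columns z of Z of
# the stratum SS applied to z. No hand-derived EMS table to get wrong.
.component_columns <- function(d, component) {
  s <- d$s; b <- d$b; g <- d$g
  site_of <- rep(seq_len(s), each = b * g)
  block_of <- rep(rep(seq_len(b), each = g), times = s) + (site_of - 1L) * b
  geno_of <- rep(seq_len(g), times = s * b)
  cell_of <- (site_of - 1L) * g + geno_of
  switch(component,
    site = lapply(seq_len(s), function(i) as.numeric(site_of == i)),
    block = lapply(seq_len(s * b), function(j) as.numeric(block_of == j)),
    genotype = lapply(d$ref_idx, function(k) as.numeric(geno_of == k)),
    interaction = lapply(seq_len(s * g), function(c) as.numeric(cell_of == c)),
    interaction_test = {
      cells <- as.vector(outer(c(d$gmo_idx, d$comp_idx), (seq_len(s) - 1L) * g, `+`))
      lapply(cells, function(c) as.numeric(cell_of == c))
    },
    interaction_reference = {
      cells <- as.vector(outer(d$ref_idx, (seq_len(s) - 1L) * g, `+`))
      lapply(cells, function(c) as.numeric(cell_of == c))
    },
    stop("unknown component ", component))
}

# coefficient matrix: rows = strata, cols = components; entry = coefficient of
# sigma2_component in E[MS_stratum] (residual handled analytically: always 1)
.ems_coefficients <- function(design, components) {
  d <- .design_dims(design)
  df <- .strata_df(d)
  C <- sapply(components, function(comp) {
    cols <- .component_columns(d, comp)
    ss_sum <- Reduce(`+`, lapply(cols, .strata_ss, d = d))
    ifelse(df > 0, ss_sum / df, NA_real_)
  })
  C <- cbind(C, residual = ifelse(df > 0, 1, NA_real_))
  rownames(C) <- .strata_names
  C
}

#' Expected mean squares of every stratum
#'
#' Closed-form expected values of the balanced-ANOVA mean squares as linear
#' combinations of the variance components, e.g. residual \eqn{\to \sigma^2_e}
#' and the site-by-genotype strata \eqn{\to \sigma^2_e + b\,\sigma^2_{SxG}}.
#' Coefficients are computed exactly from the stratum quadratic forms, so this
#' doubles as an independent oracle for [decompose_trial()] (fixed offsets
#' contribute no noncentrality here; EMS are the pure random-effect
#' expectations).
#'
#' @param design A `trial_design`.
#' @param varcomps A [variance_components()].
#' @return Data frame with columns `stratum`, `df`, `ems`.
#' @export
expected_mean_squares <- function(design, varcomps) {
  stopifnot(inherits(design, "trial_design"), inherits(varcomps, "variance_components"))
  comps <- if (varcomps$partitioned)
    c("site", "block", "genotype", "interaction_test", "interaction_reference")
  else c("site", "block", "genotype", "interaction")
  C <- .ems_coefficients(design, comps)
  sig <- c(unlist(varcomps[comps]), residual = varcomps$residual)
  ems <- as.vector(C %*% sig)
  d <- .design_dims(design)
  data.frame(stratum = .strata_names, df = as.integer(.strata_df(d)[.strata_names]),
             ems = ems, row.names = NULL, stringsAsFactors = FALSE)
}

#' Method-of-moments variance component estimates
#'
#' Inverts the expected-mean-square relations of the balanced decomposition
#' for the partitioned model (site, block, genotype-within-reference,
#' site-by-test-entry, site-by-reference, residual); any negative solution is
#' truncated to zero and flagged. A pooled site-by-genotype estimate from the
#' combined interaction stratum is reported alongside.
#'
#' @param decomp A [decompose_trial()] result.
#' @param design The trial design (defaults to the decomposition's).
#' @return A `varcomp_estimates` data frame: `component`, `estimate`
#'   (truncated at zero), `raw` (untruncated solution), `truncated` flag.
#' @export
estimate_varcomps <- function(decomp, design = attr(decomp, "design")) {
  stopifnot(inherits(decomp, "trial_anova"))
  d <- .design_dims(design)
  if (d$s * (d$b - 1L) * (d$g - 1L) <= 0)
    stop("zero residual degrees of freedom: variance components are not estimable",
         call. = FALSE)
  comps <- c("site", "block", "genotype", "interaction_test", "interaction_reference")
  C <- .ems_coefficients(design, comps)
  strata <- c("site", "block_in_site", "genotype_within_reference",
              "site_x_test", "site_x_reference", "residual")
  keep <- .strata_df(d)[strata] > 0
  strata <- strata[keep]
  cols <- c(comps, "residual")
  cols_keep <- cols %in% c("residual", "site", "block", "interaction_test") |
    (d$r >= 2 & cols %in% c("genotype", "interaction_reference"))
  A <- C[strata, cols[cols_keep], drop = FALSE]
  ms <- .anova_get(decomp, strata)
  raw <- setNames(rep(NA_real_, length(cols)), cols)
  raw[colnames(A)] <- solve(A, ms)
  est <- pmax(raw, 0)
  pooled <- .pooled_interaction(decomp)
  raw_pool <- (pooled$ms - est[["residual"]]) / d$b
  out <- data.frame(
    component = c(cols, "interaction_pooled"),
    raw = c(unname(raw), raw_pool),
    stringsAsFactors = FALSE)
  out$estimate <- pmax(out$raw, 0)
  out$truncated <- !is.na(out$raw) & out$raw < 0
  out <- out[, c("component", "estimate", "raw", "truncated")]
  structure(out, class = c("varcomp_estimates", "data.frame"), design = design)
}

#' @export
print.varcomp_estimates <- function(x, ...) {
  cat("Method-of-moments variance component estimates\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 5)
  invisible(x)
}

#' Degrees of freedom of a site-by-genotype interaction stratum
#'
#' For `s` sites and `t` genotypes the interaction carries
#' \eqn{(s-1)(t-1)} degrees of freedom; with the two test entries (GMO and
#' comparator) across 4 sites this is the 3 df that the interaction-aware
#' difference test runs on.
#'
#' @param n_sites Number of sites (\eqn{\ge 2}).
#' @param n_genotypes Number of genotypes in the stratum (\eqn{\ge 2}).
#' @return Integer degrees of freedom.
#' @examples
#' interaction_df(4, 2)  # 3
#' @export
interaction_df <- function(n_sites, n_genotypes) {
  if (!.is_count(n_sites) || n_sites < 2)
    stop("`n_sites` must be an integer >= 2", call. = FALSE)
  if (!.is_count(n_genotypes) || n_genotypes < 2)
    stop("`n_genotypes` must be an integer >= 2", call. = FALSE)
  as.integer((n_sites - 1) * (n_genotypes - 1))
}
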