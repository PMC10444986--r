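#' Shannon diversity of a proportion vector
#'
#' H' = -sum(p_i ln p_i) over species with nonzero share, in nats.  The
#' input must be a (near-)normalized proportion vector.
#'
#' @param p Nonnegative proportions summing to 1 (tolerance `tol`).
#' @param tol Normalization tolerance (default 1e-6).
#' @return Shannon diversity in nats.
#' @export
shannon_diversity <- function(p, tol = 1e-6) {
  if (any(is.na(p)) || any(p < 0)) {
    stop_florivis("proportions must be nonnegative and non-missing",
                  "florivis_validation_error")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_florivis(sprintf("proportions sum to %.8f, not 1", sum(p)),
                  "florivis_validation_error")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' J' = H' / ln(S): diversity relative to its maximum at richness S.
#' Undefined (NA) at S = 1, where ln(S) = 0.
#'
#' @param H_prime Shannon diversity (nats).
#' @param S Species richness, >= 1.
#' @return J' in \[0, 1\], or `NA` when S = 1.
#' @export
evenness <- function(H_prime, S) {
  if (any(S < 1)) {
    stop_florivis("richness must be >= 1", "florivis_domain_error")
  }
  ifelse(S == 1, NA_real_, H_prime / log(S))
}

#' Annual diversity panel of resource-supplying and insect-visited flowers
#'
#' For each site, study year and measure of an annual contribution table,
#' computes Shannon diversity H', nonzero-share richness and evenness J'.
#' Measures are relabelled with the panel's category codes: Sug (nectar
#' sugar), Pol (pollen), AP (all wild insects pooled), WB (wild bees and
#' wasps), HF (hoverflies), BF (butterflies).
#'
#' @param annual An [annual_contributions()] table.
#' @param evenness_s `"category"` (default) divides H' by the log of the
#'   category's own nonzero richness; `"site_total"` uses the union richness
#'   across all categories of the same site and year.
#' @return A tibble `site, study_year, category, H_prime, richness,
#'   J_prime`.
#' @export
annual_diversity_panel <- function(annual,
                                   evenness_s = c("category", "site_total")) {
  evenness_s <- match.arg(evenness_s)
  annual <- tibble::as_tibble(annual)
  nz <- annual[annual$proportion > 0, , drop = FALSE]

  site_totals <- dplyr::summarise(
    dplyr::group_by(nz, .data$site, .data$period),
    S_site = dplyr::n_distinct(.data$species_id), .groups = "drop")

  grp <- dplyr::group_by(nz, .data$site, .data$period, .data$measure)
  out <- dplyr::summarise(grp,
                          H_prime = shannon_diversity(.data$proportion),
                          richness = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(out, site_totals, by = c("site", "period"))
  S <- if (evenness_s == "category") out$richness else out$S_site
  out$J_prime <- evenness(out$H_prime, S)
  tibble::tibble(
    site = out$site,
    study_year = out$period,
    category = unname(CATEGORY_CODES[out$measure]),
    H_prime = out$H_prime,
    richness = as.integer(out$richness),
    J_prime = out$J_prime
  )
}

#' Tukey HSD comparison of diversity across categories
#'
#' Tests, within one study year, whether Shannon diversity differs between
#' the resource and visitation categories, treating sites as replicates of a
#' one-way layout (factor = category).  Pairwise differences use Tukey's
#' honestly-significant-difference adjustment (studentized range); a compact
#' letter display summarizes the significance groups.
#'
#' @param panel An [annual_diversity_panel()] tibble.
#' @param year Study year to test (1 or 2).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list of class `tukey_comparison`: `pairs` (tibble `cat_a,
#'   cat_b, diff, lwr, upr, p_adj`), `letters` (tibble `category, mean,
#'   letters`), `year`, `alpha`.
#' @export
tukey_compare <- function(panel, year, alpha = 0.05) {
  d <- panel[panel$study_year == year, , drop = FALSE]
  reps <- table(d$category)
  if (length(reps) < 2 || any(reps < 2)) {
    stop_florivis("need >= 2 categories each with >= 2 replicate sites",
                  "florivis_replication_error")
  }
  d$category <- factor(d$category)
  fit <- aov(H_prime ~ category, data = d)
  tk <- TukeyHSD(fit, "category")$category
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble::tibble(
    cat_a = vapply(nm, `[`, "", 1),
    cat_b = vapply(nm, `[`, "", 2),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"])
  )
  # zero residual variance with zero difference: identical groups, p = 1
  degen <- is.nan(pairs$p_adj) & pairs$diff == 0
  pairs$p_adj[degen] <- 1
  means <- sort(tapply(d$H_prime, d$category, mean), decreasing = TRUE)
  letters <- compact_letters(names(means), pairs, alpha)
  structure(list(
    pairs = pairs,
    letters = tibble::tibble(category = names(means), mean = unname(means),
                             letters = unname(letters[names(means)])),
    year = year, alpha = alpha
  ), class = "tukey_comparison")
}

#' @export
print.tukey_comparison <- function(x, ...) {
  cat(sprintf("<tukey_comparison> study year %s (alpha = %g)\n", x$year,
              x$alpha))
  print(as.data.frame(x$letters), row.names = FALSE)
  invisible(x)
}

# Compact letter display: each maximal clique of the non-significance graph
# receives one letter; a category shows every letter of the cliques it
# belongs to.  Letters ordered by decreasing group mean of their cliques.
compact_letters <- function(categories, pairs, alpha) {
  k <- length(categories)
  adj <- matrix(FALSE, k, k, dimnames = list(categories, categories))
  diag(adj) <- TRUE
  ns <- pairs[pairs$p_adj >= alpha, , drop = FALSE]
  for (i in seq_len(nrow(ns))) {
    adj[ns$cat_a[i], ns$cat_b[i]] <- TRUE
    adj[ns$cat_b[i], ns$cat_a[i]] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  # order cliques by the best-ranked (first-listed) member for stable letters
  rank <- setNames(seq_along(categories), categories)
  ord <- order(vapply(cliques, function(cl) min(rank[names(cl)]), 0))
  cliques <- cliques[ord]
  out <- setNames(rep("", k), categories)
  for (j in seq_along(cliques)) {
    members <- names(cliques[[j]])
    out[members] <- paste0(out[members], letters[j])
  }
  out
}
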