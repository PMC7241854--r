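# Cross-species comparison of gene copy-number profiles over ortholog pairs
# and permutation tests: conservation of non-diploidy between species and
# enrichment of disease-annotated genes among non-diploid (or
# profile-changed) genes.

profile_class <- function(category) {
  ifelse(grepl("_FD$", category), "FD",
         ifelse(grepl("_CNV$", category), "CNV",
                ifelse(category == "diploid", "diploid", "unclassified")))
}

#' Crosstab of gene profiles over ortholog pairs
#'
#' Counts ortholog pairs by the (species A category, species B category)
#' combination. Pairs whose genes lack a profile in either species are
#' reported separately, not counted.
#'
#' @param pairs data frame `gene_a`, `gene_b` and optionally `one_to_one`
#'   (logical).
#' @param profiles_a,profiles_b gene-profile tables (`gene`, `category`).
#' @param one_to_one_only restrict to one-to-one pairs (default TRUE when
#'   the column is present).
#' @return list: `crosstab` (table), `n_scored`, `n_unresolved`.
#' @export
crosstab_profiles <- function(pairs, profiles_a, profiles_b,
                              one_to_one_only = TRUE) {
  if (anyDuplicated(paste(pairs$gene_a, pairs$gene_b)))
    stop("duplicate ortholog pairs")
  if (one_to_one_only && "one_to_one" %in% names(pairs))
    pairs <- pairs[as.logical(pairs$one_to_one), , drop = FALSE]
  ca <- profiles_a$category[match(pairs$gene_a, profiles_a$gene)]
  cb <- profiles_b$category[match(pairs$gene_b, profiles_b$gene)]
  resolved <- !is.na(ca) & !is.na(cb)
  lev <- union(GENE_CATEGORIES, unique(c(ca[resolved], cb[resolved])))
  tab <- table(factor(ca[resolved], levels = lev),
               factor(cb[resolved], levels = lev), dnn = c("A", "B"))
  list(crosstab = tab, n_scored = sum(resolved),
       n_unresolved = sum(!resolved))
}

perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (length(null) + 1)
}

#' Permutation test for conservation of non-diploidy
#'
#' After excluding diploid-diploid pairs, the observed statistic is the
#' number of ortholog pairs whose two members are non-diploid of matching
#' class (both FD-related or both CNV-related; `match = "exact"` requires
#' identical categories). The null shuffles one species' categories across
#' the retained genes `n_perm` times; the p-value uses the add-one
#' estimator `(1 + #{null >= obs}) / (n_perm + 1)`, so it is never zero.
#'
#' @param pair_categories data frame `cat_a`, `cat_b` (gene categories of
#'   each ortholog pair).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @param match `"class"` (default; FD/CNV granularity) or `"exact"`.
#' @return list: `observed`, `n_pairs` (retained), `n_perm`, `p_value`,
#'   `seed`.
#' @export
permutation_conservation <- function(pair_categories, n_perm = 10000L,
                                     seed = 1L, match = c("class", "exact")) {
  match <- match.arg(match)
  ca <- pair_categories$cat_a
  cb <- pair_categories$cat_b
  keep <- !(ca == "diploid" & cb == "diploid")
  if (!any(keep)) stop("no non-diploid-diploid pairs")
  ca <- ca[keep]
  cb <- cb[keep]
  # shuffling categories and shuffling their precomputed class/label codes
  # are equivalent; precomputing keeps the permutation loop cheap
  if (match == "class") {
    a <- profile_class(ca)
    b <- profile_class(cb)
    stat <- function(a, b) sum(a == b & a %in% c("FD", "CNV"))
  } else {
    a <- ifelse(ca == "diploid" | grepl("unclassified", ca), NA, ca)
    b <- cb
    stat <- function(a, b) sum(!is.na(a) & a == b, na.rm = TRUE)
  }
  observed <- stat(a, b)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat(a, sample(b)), numeric(1L))
  list(observed = observed, n_pairs = length(ca), n_perm = n_perm,
       p_value = perm_pvalue(observed, null), seed = seed)
}

#' Permutation test for disease-gene enrichment
#'
#' The observed statistic is the number of scope-qualifying genes (scope
#' `"nondiploid"`: any non-diploid profile; scope `"profile_change"`:
#' ortholog pairs whose two species' profile classes differ) that carry a
#' disease annotation. The null shuffles the qualifying labels across the
#' gene universe; same p-value estimator as
#' [permutation_conservation()]. Disease tables mixing sources should be
#' filtered upstream (see [read_disease_table()]; DisGeNET rows at score >=
#' 0.06).
#'
#' @param profiles gene-profile table of the focal species.
#' @param disease_genes character vector of disease-annotated gene ids.
#' @param scope `"nondiploid"` or `"profile_change"`.
#' @param pairs,profiles_b required for scope `"profile_change"`: ortholog
#'   pairs (`gene_a`, `gene_b`) and the other species' profiles; the
#'   universe is then the paired genes of the focal species.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return list: `observed`, `n_qualifying`, `n_universe`, `n_perm`,
#'   `p_value`, `seed`.
#' @export
permutation_disease_enrichment <- function(profiles, disease_genes,
                                           scope = c("nondiploid", "profile_change"),
                                           pairs = NULL, profiles_b = NULL,
                                           n_perm = 10000L, seed = 1L) {
  scope <- match.arg(scope)
  if (length(disease_genes) == 0L) stop("empty disease set")
  if (scope == "nondiploid") {
    universe <- profiles$gene
    qualifying <- profiles$category != "diploid"
  } else {
    stopifnot(!is.null(pairs), !is.null(profiles_b))
    ca <- profiles$category[match(pairs$gene_a, profiles$gene)]
    cb <- profiles_b$category[match(pairs$gene_b, profiles_b$gene)]
    ok <- !is.na(ca) & !is.na(cb)
    universe <- pairs$gene_a[ok]
    qualifying <- profile_class(ca[ok]) != profile_class(cb[ok])
  }
  disease <- universe %in% disease_genes
  observed <- sum(qualifying & disease)
  nq <- sum(qualifying)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    sum(disease[sample.int(length(universe), nq)])
  }, numeric(1L))
  list(observed = observed, n_qualifying = nq, n_universe = length(universe),
       n_perm = n_perm, p_value = perm_pvalue(observed, null), seed = seed)
}

#' Read a disease-annotation table
#'
#' TSV with columns `gene`, `source`, `score`. Rows from score-bearing
#' curated sources (e.g. DisGeNET) are kept only when `score >=
#' min_score` (default 0.06, the curated-association cutoff); rows without
#' a score (e.g. GWAS catalog, where both reported and mapped gene columns
#' should already be unioned into `gene`) are always kept.
#'
#' @param path TSV path.
#' @param min_score score cutoff (default 0.06).
#' @param source optional source filter (e.g. `"DisGeNET"`).
#' @return character vector of disease gene ids.
#' @export
read_disease_table <- function(path, min_score = 0.06, source = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "source", "score") %in% names(tab)))
  if (!is.null(source)) tab <- tab[tab$source %in% source, , drop = FALSE]
  keep <- is.na(tab$score) | tab$score >= min_score
  unique(tab$gene[keep])
}
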