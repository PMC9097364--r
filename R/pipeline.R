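# Synthesis of the four proxies into a final permitted/excluded diet set
# per fossil taxon.  Each proxy yields a verdict (excluded categories and,
# for classifier proxies, ranked posteriors); the consensus permits the
# complement of the union of exclusions and ranks the permitted categories
# by mean normalised posterior.  Exclusion always wins over a high
# posterior, but the conflict is logged, never silently dropped.

#' Build a proxy verdict
#'
#' @param proxy One of `"mass"`, `"tm"`, `"ma"`, `"fea"`.
#' @param excluded Named list (by taxon) of excluded category vectors.
#' @param posteriors Optional named list (by taxon) of named posterior
#'   vectors over diet categories.
#' @param notes Free-text evidence notes.
#' @return Object of class `proxy_verdict`.
#' @export
proxy_verdict <- function(proxy, excluded, posteriors = NULL, notes = NULL) {
  proxy <- match.arg(proxy, c("mass", "tm", "ma", "fea"))
  structure(list(proxy = proxy, excluded = excluded, posteriors = posteriors,
                 notes = notes),
            class = "proxy_verdict")
}

#' Mass proxy: vectorised mass-rule exclusions
#'
#' @param masses Named list (by taxon) of `mass_estimate`s.
#' @return A `proxy_verdict` with per-taxon exclusions from [mass_rule()].
#' @export
run_mass_proxy <- function(masses) {
  proxy_verdict("mass", excluded = lapply(masses, mass_rule))
}

#' Classifier proxy: discriminant posteriors for fossils
#'
#' Fits LDA or DAPC on labelled extant rows, predicts fossils as
#' supplementary rows, and excludes categories whose posterior falls below
#' `posterior_floor` (only when `exclude_by_floor` is enabled; exclusion by
#' a classifier is deliberately conservative).  The top-posterior class is
#' never excluded.
#'
#' @param X Extant trait matrix.
#' @param groups Extant diet labels.
#' @param fossils Fossil trait matrix (same columns).
#' @param method `"lda"` or `"dapc"`.
#' @param proxy Proxy id recorded in the verdict (`"fea"`, `"ma"` or
#'   `"tm"`).
#' @param posterior_floor Posterior below which a category may be excluded.
#' @param exclude_by_floor Enable floor-based exclusion.
#' @param ... Passed to [lda_shared()] or [dapc()].
#' @return A `proxy_verdict` with posteriors and (optionally) exclusions.
#' @export
run_classifier_proxy <- function(X, groups, fossils, method = c("lda", "dapc"),
                                 proxy = "fea", posterior_floor = 0.05,
                                 exclude_by_floor = TRUE, ...) {
  method <- match.arg(method)
  fit <- if (method == "lda")
    lda_shared(X, groups, supplementary = fossils, ...)
  else dapc(X, groups, supplementary = fossils, ...)
  post <- fit$supplementary_posterior
  taxa <- rownames(fossils) %||% paste0("fossil", seq_len(nrow(fossils)))
  posteriors <- stats::setNames(
    lapply(seq_len(nrow(post)), function(i) post[i, ]), taxa)
  excluded <- lapply(posteriors, function(p) {
    if (!exclude_by_floor) return(character(0))
    top <- names(p)[which.max(p)]
    setdiff(names(p)[p < posterior_floor], top)
  })
  proxy_verdict(proxy, excluded = excluded, posteriors = posteriors)
}

#' Synthesise proxy verdicts into a consensus diet assignment
#'
#' For each taxon: permitted = all categories minus the union of
#' exclusions across proxies; the shortlist ranks permitted categories by
#' their mean normalised posterior across the classifier proxies (taxa with
#' no classifier posterior keep the permitted set unranked).  A proxy whose
#' top-posterior class is excluded by another proxy produces a conflict log
#' entry; exclusion wins.
#'
#' @param verdicts List of `proxy_verdict`s.
#' @param categories Category universe (default [diet_categories()]).
#' @return Object of class `consensus_result`: per-taxon `permitted`,
#'   `shortlist`, `conflicts` (data frame), `provenance`.
#' @export
synthesize <- function(verdicts, categories = diet_categories()) {
  taxa <- unique(unlist(lapply(verdicts, function(v)
    union(names(v$excluded), names(v$posteriors)))))
  if (!length(taxa)) stop("no taxa in any verdict")
  permitted <- list(); shortlist <- list(); prov <- list()
  conflicts <- data.frame(taxon = character(0), proxy = character(0),
                          top_class = character(0),
                          excluded_by = character(0))
  for (tx in taxa) {
    excl <- character(0)
    excl_by <- list()
    for (v in verdicts) {
      e <- v$excluded[[tx]]
      if (length(e)) {
        excl <- union(excl, e)
        for (cat in e) excl_by[[cat]] <- union(excl_by[[cat]], v$proxy)
      }
    }
    perm <- setdiff(categories, excl)
    # mean normalised posterior over classifier proxies
    posts <- lapply(verdicts, function(v) v$posteriors[[tx]])
    posts <- posts[!vapply(posts, is.null, logical(1))]
    rank_score <- NULL
    if (length(posts)) {
      aligned <- vapply(posts, function(p) {
        q <- stats::setNames(rep(0, length(categories)), categories)
        q[names(p)] <- p / sum(p)
        q
      }, numeric(length(categories)))
      rank_score <- rowMeans(aligned)
      for (v in verdicts) {
        p <- v$posteriors[[tx]]
        if (is.null(p)) next
        top <- names(p)[which.max(p)]
        if (top %in% excl)
          conflicts <- rbind(conflicts, data.frame(
            taxon = tx, proxy = v$proxy, top_class = top,
            excluded_by = paste(excl_by[[top]], collapse = "+")))
      }
    }
    short <- if (is.null(rank_score)) perm
             else perm[order(rank_score[perm], decreasing = TRUE)]
    permitted[[tx]] <- perm
    shortlist[[tx]] <- short
    prov[[tx]] <- excl_by
  }
  structure(list(permitted = permitted, shortlist = shortlist,
                 conflicts = conflicts, provenance = prov),
            class = "consensus_result")
}

#' @exportS3Method base::print
print.consensus_result <- function(x, ...) {
  for (tx in names(x$shortlist)) {
    cat(tx, ": shortlist [",
        paste(utils::head(x$shortlist[[tx]], 5), collapse = ", "),
        if (length(x$shortlist[[tx]]) > 5) ", ..." else "", "]\n", sep = "")
  }
  if (nrow(x$conflicts))
    cat(nrow(x$conflicts), "conflict(s) logged; exclusions took precedence\n")
  invisible(x)
}
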