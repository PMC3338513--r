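#' Hypergeometric tail probability of a chain
#'
#' For a chain of `k` successive genes (counting interstitials) of which `l`
#' share an annotation carried by `m` genes in a genome of `N`, returns the
#' probability that at least `l` of `k` genes drawn without replacement from
#' the genome are carriers:
#' \deqn{P(X \ge l) = \sum_{i=l}^{\min(k,m)} \binom{m}{i}\binom{N-m}{k-i} / \binom{N}{k}.}
#' Computed with the exact hypergeometric survival function, so small tail
#' probabilities do not underflow to zero prematurely.
#'
#' Arguments are recycled to a common length.
#'
#' @param N genome size (total gene count).
#' @param m number of genes in the genome carrying the annotation.
#' @param k chain span in genes, including interstitial genes.
#' @param l number of chain members sharing the annotation.
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_tail(10, 3, 3, 3) # 1 / choose(10, 3)
hypergeom_tail <- function(N, m, k, l) {
  n_out <- max(length(N), length(m), length(k), length(l))
  N <- rep_len(as.numeric(N), n_out)
  m <- rep_len(as.numeric(m), n_out)
  k <- rep_len(as.numeric(k), n_out)
  l <- rep_len(as.numeric(l), n_out)
  if (any(is.na(N) | is.na(m) | is.na(k) | is.na(l))) {
    abort("hypergeom_tail: parameters must be non-missing")
  }
  if (any(m < 0 | m > N)) abort("hypergeom_tail: require 0 <= m <= N")
  if (any(l < 0 | l > k | k > N)) abort("hypergeom_tail: require 0 <= l <= k <= N")
  phyper(l - 1, m, N - m, k, lower.tail = FALSE)
}

#' Score chains with the hypergeometric model and expectation correction
#'
#' For every chain, computes the tail probability [hypergeom_tail()] for
#' each term in its common-annotation subset (using that term's genome-wide
#' frequency `m`) and keeps the *largest* of these p-values, the most
#' conservative choice when members share several annotations. The
#' expectation value corrects for the genome-wide number of opportunities to
#' observe such a chain, which for all practical purposes equals the number
#' of genes: `e = p * N`.
#'
#' @param chains a `chain_table` from [detect_chains()].
#' @param annotations the annotation tibble the chains were detected from
#'   (used for term frequencies).
#' @param index the `genome_index` (provides `N`).
#' @return the chain table with columns `p_value`, `e_value`, `m_used`,
#'   `term_used` added.
#' @export
score_chains <- function(chains, annotations, index) {
  n_genes <- nrow(index)
  if (nrow(chains) == 0) {
    chains$p_value <- numeric(0)
    chains$e_value <- numeric(0)
    chains$m_used <- integer(0)
    chains$term_used <- character(0)
    return(chains)
  }
  freq <- term_frequencies(annotations)
  freq_key <- setNames(freq$m, paste(freq$dataset, freq$term_id, sep = "\r"))

  scored <- pmap(
    list(chains$dataset, chains$common_terms, chains$k, chains$l),
    function(ds, terms, k, l) {
      if (length(terms) == 0) abort("chain has an empty common-annotation subset")
      terms <- sort(terms)
      m <- unname(freq_key[paste(ds, terms, sep = "\r")])
      if (any(is.na(m))) {
        abort(paste0(
          "term(s) missing from genome-wide frequencies: ",
          paste(terms[is.na(m)], collapse = ", ")
        ))
      }
      p <- hypergeom_tail(n_genes, m, k, l)
      i <- which.max(p)
      list(p = p[i], m = as.integer(m[i]), term = terms[i])
    }
  )
  chains$p_value <- map_dbl(scored, "p")
  chains$e_value <- chains$p_value * n_genes
  chains$m_used <- map_int(scored, "m")
  chains$term_used <- map_chr(scored, "term")
  chains
}

#' Filter chains at an expectation threshold
#'
#' Keeps chains with `e_value < threshold`. The default threshold of 0.01
#' practically eliminates cluster detection in randomised genomes; the
#' larger thresholds (0.05, 0.1, 0.15) are provided for sensitivity sweeps.
#'
#' @param chains a scored chain table (see [score_chains()]).
#' @param threshold expectation-value cutoff; chains strictly below it are
#'   kept. Default 0.01.
#' @return the significant subset of `chains`.
#' @export
filter_significant <- function(chains, threshold = 0.01) {
  if (!"e_value" %in% names(chains)) {
    abort("chains must be scored with score_chains() before filtering")
  }
  chains[chains$e_value < threshold, , drop = FALSE]
}
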