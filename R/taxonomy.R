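#' The 20-class organism taxonomy vocabulary
#'
#' Fixed vocabulary of high-level organism lineage classes used for one-hot
#' encoding: 8 viral realms/classes, 5 eukaryotic supergroups and 7
#' bacterial clades. The order is fixed because one-hot slots are
#' positional.
#'
#' @return A `data.frame` with columns `class` and `superkingdom`,
#'   20 rows, in the canonical slot order.
#' @examples
#' taxonomy_vocabulary()$class
#' @export
taxonomy_vocabulary <- function() {
  data.frame(
    class = c(
      # Virus (8)
      "Riboviria", "Duplodnaviria", "Monodnaviria", "Varidnaviria",
      "Ribozyviria", "Anelloviridae", "Naldaviricetes", "Adnaviria",
      # Eukaryota (5)
      "Metamonada", "Discoba", "Sar", "Viridiplantae", "Opisthokonta",
      # Bacteria (7)
      "Terrabacteria group", "Proteobacteria", "PVC group", "Spirochaetes",
      "FCB group", "Thermodesulfobacteria", "Fusobacteria"
    ),
    superkingdom = rep(c("Virus", "Eukaryota", "Bacteria"), c(8L, 5L, 7L)),
    stringsAsFactors = FALSE
  )
}

#' One-hot encode an organism lineage class
#'
#' Encodes a lineage class as a binary vector over the 20 vocabulary slots.
#' `"unknown"` maps to the all-zero vector by convention, so peptides
#' without organism metadata carry no taxonomy signal rather than a fake
#' class.
#'
#' @param organism_class A vocabulary class name or `"unknown"`.
#' @param vocab Vocabulary as returned by [taxonomy_vocabulary()].
#' @return Named numeric vector of length 20 (names `taxon.<class>`,
#'   spaces replaced by `_`).
#' @examples
#' v <- taxonomy_onehot("Riboviria")
#' sum(v)  # 1
#' sum(taxonomy_onehot("unknown"))  # 0
#' @export
taxonomy_onehot <- function(organism_class, vocab = taxonomy_vocabulary()) {
  stopifnot(length(organism_class) == 1L)
  out <- stats::setNames(numeric(nrow(vocab)),
                         paste0("taxon.", gsub(" ", "_", vocab$class)))
  if (identical(organism_class, "unknown"))
    return(out)
  slot <- match(organism_class, vocab$class)
  if (is.na(slot))
    stop("organism class ", sQuote(organism_class),
         " is not in the taxonomy vocabulary (use \"unknown\" for missing)",
         call. = FALSE)
  out[slot] <- 1
  out
}
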