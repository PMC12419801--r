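#' Transmembrane-tendency residue scale
#'
#' The published transmembrane-tendency hydropathy scale of Zhao & London
#' (2006, Protein Science 15:1987-2001), derived from the compositional bias
#' of transmembrane versus soluble segments. Positive values mark residues
#' favoured in membrane-spanning helices; the scale is constructed so that
#' typical soluble sequences average below zero and typical TM helices above.
#'
#' @param ambiguity_policy How to treat residues absent from the scale
#'   (X, B, Z, U, O, gaps): `"skip"` drops them from the average (count
#'   reported via a message), `"error"` aborts.
#' @return A `tm_scale` object: a named numeric vector over the 20 canonical
#'   amino acids with attributes `name` and `ambiguity_policy`.
#' @references Zhao G, London E (2006). An amino acid "transmembrane
#'   tendency" scale that approaches the theoretical limit to accuracy for
#'   prediction of transmembrane helices. Protein Science 15:1987-2001.
#' @export
#' @examples
#' sc <- tm_tendency_scale()
#' sc["F"]  # most TM-propense residue
tm_tendency_scale <- function(ambiguity_policy = c("skip", "error")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  values <- c(
    A =  0.38, R = -2.57, N = -1.62, D = -3.27, C = -0.30,
    Q = -1.84, E = -2.90, G = -0.19, H = -1.44, I =  1.97,
    L =  1.82, K = -3.46, M =  1.40, F =  1.98, P = -1.44,
    S = -0.53, T = -0.32, W =  1.53, Y =  0.49, V =  1.46
  )
  tm_scale(values, name = "transmembrane_tendency_zhao_london_2006",
           ambiguity_policy = ambiguity_policy)
}

#' Construct a residue propensity scale
#'
#' @param values Named numeric vector; names must cover all 20 canonical
#'   amino-acid letters and values must be finite.
#' @param name Scale identifier.
#' @param ambiguity_policy `"skip"` or `"error"` for non-canonical residues.
#' @return A `tm_scale` object.
#' @export
tm_scale <- function(values, name = "custom",
                     ambiguity_policy = c("skip", "error")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  canonical <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  fc_assert(is.numeric(values) && !is.null(names(values)),
            "scale values must be a named numeric vector")
  missing <- setdiff(canonical, names(values))
  fc_assert(length(missing) == 0L,
            sprintf("scale is missing canonical residue(s): %s",
                    paste(missing, collapse = ", ")))
  fc_assert(all(is.finite(values)), "scale values must all be finite")
  structure(values[canonical], class = "tm_scale", name = name,
            ambiguity_policy = ambiguity_policy)
}

#' @export
print.tm_scale <- function(x, ...) {
  cat(sprintf("<tm_scale> %s (ambiguity: %s)\n",
              attr(x, "name"), attr(x, "ambiguity_policy")))
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}
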