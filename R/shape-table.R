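#' Pentamer DNA-shape lookup tables
#'
#' DNA shape features are attached to sequence through a pentamer lookup:
#' every 5-mer is mapped to four structural parameters -- minor groove width
#' (MGW, in Angstrom), propeller twist (ProT, degrees), roll (Roll, degrees)
#' and helix twist (HelT, degrees) -- assigned to the pentamer's *center*
#' base. Step parameters (Roll, HelT) are collapsed to a single scalar at the
#' center position. Lookups use the table exactly as given; no
#' reverse-complement symmetrization is applied.
#'
#' `synthetic_shape_table()` builds a **synthetic** table: it is not derived
#' from any published shape-query server or crystallographic compilation.
#' Values follow an additive base-at-position model (A/T narrow the minor
#' groove, G/C widen it, with the center base weighted most) plus a small
#' seeded pentamer-specific deviation, clipped to physically plausible
#' ranges. This preserves the property the downstream classifier relies on --
#' flanking base composition propagates into core-adjacent shape -- while
#' being fully reproducible and self-contained.
#'
#' `uniform_shape_table()` assigns the same four values to every pentamer and
#' is useful for degenerate-case tests (shape carries no information).
#'
#' @param seed integer seed; the table is a pure function of it.
#' @param MGW,ProT,Roll,HelT constants used by `uniform_shape_table()`.
#' @return A data.frame with columns `pentamer`, `MGW`, `ProT`, `Roll`,
#'   `HelT` and 1024 rows (all pentamers over ACGT).
#' @examples
#' tab <- synthetic_shape_table()
#' range(tab$MGW)
#' @export
synthetic_shape_table <- function(seed = 202L) {
  pent <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 5L)
  chars <- matrix(unlist(strsplit(pent, "")), ncol = 5L, byrow = TRUE)
  spec <- list(
    MGW  = list(base = c(A = -0.45, C = 0.45, G = 0.45, T = -0.45),
                w = c(0.4, 0.8, 1.0, 0.8, 0.4), mu = 5.1, sd = 0.12,
                lo = 2.8, hi = 6.4),
    ProT = list(base = c(A = -3.2, C = 2.8, G = 2.8, T = -3.2),
                w = c(0.3, 0.7, 1.0, 0.7, 0.3), mu = -6.5, sd = 0.8,
                lo = -17, hi = 0),
    Roll = list(base = c(A = -1.8, C = 1.5, G = 1.4, T = -1.6),
                w = c(0.2, 0.8, 1.0, 0.8, 0.2), mu = 1.5, sd = 0.5,
                lo = -8, hi = 9),
    HelT = list(base = c(A = 0.9, C = -0.7, G = -0.8, T = 1.0),
                w = c(0.3, 0.6, 1.0, 0.6, 0.3), mu = 34.3, sd = 0.25,
                lo = 30, hi = 38)
  )
  out <- data.frame(pentamer = pent, stringsAsFactors = FALSE)
  withr::with_seed(stage_seed(seed, "shape_table"), {
    for (feat in names(spec)) {
      s <- spec[[feat]]
      add <- rowSums(sapply(seq_len(5L), function(p) s$w[p] * s$base[chars[, p]]))
      v <- s$mu + add + rnorm(length(pent), 0, s$sd)
      out[[feat]] <- pmin(pmax(v, s$lo), s$hi)
    }
  })
  out
}

#' @rdname synthetic_shape_table
#' @export
uniform_shape_table <- function(MGW = 5.0, ProT = -7.0, Roll = 2.0,
                                HelT = 34.0) {
  pent <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 5L)
  data.frame(pentamer = pent, MGW = MGW, ProT = ProT, Roll = Roll,
             HelT = HelT, stringsAsFactors = FALSE)
}

validate_shape_table <- function(table) {
  need <- c("pentamer", "MGW", "ProT", "Roll", "HelT")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stopf("shape table must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (anyDuplicated(table$pentamer))
    stopf("shape table has duplicated pentamers")
  m <- as.matrix(table[, c("MGW", "ProT", "Roll", "HelT")])
  rownames(m) <- table$pentamer
  m
}
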