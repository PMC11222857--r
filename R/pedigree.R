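#' Build and validate a pedigree table
#'
#' @param individual_id,sire_id,dam_id character vectors; founders have
#'   `NA` (or `"0"`) parents. Parents must appear before their offspring.
#' @param generation integer generation number (founders are generation 0);
#'   inferred as 1 + max(parent generations) when omitted.
#' @return A tibble of class `pedigree`.
#' @export
pedigree <- function(individual_id, sire_id = NA, dam_id = NA,
                     generation = NULL) {
  sire_id <- as.character(sire_id)
  dam_id <- as.character(dam_id)
  sire_id[sire_id %in% "0"] <- NA_character_
  dam_id[dam_id %in% "0"] <- NA_character_
  ped <- tibble::tibble(
    individual_id = as.character(individual_id),
    sire_id = rep_len(sire_id, length(individual_id)),
    dam_id = rep_len(dam_id, length(individual_id))
  )
  if (anyDuplicated(ped$individual_id)) abort("duplicate individual_id in pedigree")
  if (xor(is.na(ped$sire_id), is.na(ped$dam_id)) |> any()) {
    abort("individuals must have both parents known or both unknown")
  }
  pos <- seq_len(nrow(ped))
  sp <- match(ped$sire_id, ped$individual_id)
  dp <- match(ped$dam_id, ped$individual_id)
  bad <- (!is.na(ped$sire_id) & (is.na(sp) | sp >= pos)) |
    (!is.na(ped$dam_id) & (is.na(dp) | dp >= pos))
  if (any(bad)) {
    abort(sprintf("parent of %s not defined earlier in the pedigree",
                  ped$individual_id[which(bad)[1]]))
  }
  if (is.null(generation)) {
    gen <- integer(nrow(ped))
    for (i in pos) {
      if (!is.na(sp[i])) gen[i] <- 1L + max(gen[sp[i]], gen[dp[i]])
    }
    ped$generation <- gen
  } else {
    ped$generation <- as.integer(rep_len(generation, nrow(ped)))
  }
  class(ped) <- c("pedigree", class(tibble::tibble()))
  ped
}

#' Wright's pedigree inbreeding coefficient
#'
#' The probability that the two alleles at a locus are identical by descent,
#' computed by the recursive-kinship formulation: an individual's inbreeding
#' coefficient equals the kinship of its parents. Founders have F = 0.
#'
#' @param ped a [pedigree()] table.
#' @param individual_id one or more individuals; defaults to all.
#' @return A tibble with `individual_id` and `expected_f`.
#' @export
#' @examples
#' ped <- pedigree(c("A", "B", "X", "Y", "Z"),
#'                 c(NA, NA, "A", "A", "X"),
#'                 c(NA, NA, "B", "B", "Y"))
#' expected_f_pedigree(ped, "Z") # full-sib offspring: 0.25
expected_f_pedigree <- function(ped, individual_id = NULL) {
  individual_id <- individual_id %||% ped$individual_id
  if (!all(individual_id %in% ped$individual_id)) {
    abort("unknown individual in pedigree")
  }
  idx <- stats::setNames(seq_len(nrow(ped)), ped$individual_id)
  sire <- match(ped$sire_id, ped$individual_id)
  dam <- match(ped$dam_id, ped$individual_id)
  memo <- new.env(parent = emptyenv())

  kin <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(min(a, b), max(a, b))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      0.5 * (1 + kin(sire[a], dam[a]))
    } else {
      # recurse through the later-listed individual (its parents are earlier)
      if (a < b) { tmp <- a; a <- b; b <- tmp }
      if (is.na(sire[a])) 0 else 0.5 * (kin(sire[a], b) + kin(dam[a], b))
    }
    memo[[key]] <- val
    val
  }
  f <- vapply(idx[individual_id], function(i) kin(sire[i], dam[i]), numeric(1))
  tibble::tibble(individual_id = individual_id, expected_f = unname(f))
}
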