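#' Load an EQ-5D-3L value set
#'
#' Reads an additive-decrement EQ-5D-3L tariff from a CSV file. The packaged
#' default is the UK social tariff estimated from time-trade-off valuations,
#' under which utilities span \[-0.594, 1\] with full health (profile 11111)
#' anchored at 1. The file must carry a provenance header (source and
#' transcription date as comment lines) and a `checksum` line equal to the sum
#' of `round(1000 * value)` over all terms; the loader refuses a file whose
#' checksum does not match, so a silently corrupted tariff can never be used
#' to score utilities.
#'
#' @param path Path to a value-set CSV with columns `term` (one of
#'   `constant`, `decrement`), `dimension`, `level`, `value`. Decrement rows
#'   cover levels 2 and 3 of the five dimensions plus the `any_level3` term.
#'   Defaults to the packaged UK tariff.
#' @return A list of class `eq5d_value_set` with elements `constant`,
#'   `decrements` (5 x 2 matrix, dimensions x levels 2:3), `n3` (any-level-3
#'   decrement), and `range` (attainable utility range).
#' @examples
#' vs <- eq5d_value_set()
#' eq5d_utility(c(1, 1, 1, 1, 1), vs) # full health: 1
#' @export
eq5d_value_set <- function(path = tc_extdata("eq5d3l_uk_tto_value_set.csv")) {
  if (!file.exists(path)) {
    abort(paste0(
      "EQ-5D value-set file not found at '", path, "'. The utility scorer ",
      "requires a tariff file with a provenance header and checksum."
    ))
  }
  header <- readLines(path, n = 20L)
  header <- header[startsWith(header, "#")]
  chk_line <- grep("checksum:", header, value = TRUE)
  if (length(chk_line) != 1L) {
    abort("value-set file lacks the mandatory '# checksum:' provenance line")
  }
  declared <- as.integer(sub(".*checksum:\\s*", "", chk_line))
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("term", "dimension", "level", "value") %in% names(tab)))
  observed <- sum(round(1000 * tab$value))
  if (!identical(as.integer(observed), declared)) {
    abort(paste0(
      "value-set checksum mismatch (declared ", declared, ", file sums to ",
      observed, "); refusing to score utilities from a corrupted tariff"
    ))
  }

  dims <- c("mobility", "selfcare", "usual_activities",
            "pain_discomfort", "anxiety_depression")
  dec <- matrix(0, nrow = 5L, ncol = 2L,
                dimnames = list(dims, c("2", "3")))
  dtab <- tab[tab$term == "decrement" & tab$dimension %in% dims, ]
  for (i in seq_len(nrow(dtab))) {
    dec[dtab$dimension[i], as.character(dtab$level[i])] <- dtab$value[i]
  }
  n3 <- tab$value[tab$term == "decrement" & tab$dimension == "any_level3"]
  const <- tab$value[tab$term == "constant"]
  if (length(n3) != 1L || length(const) != 1L) {
    abort("value-set file must contain exactly one constant and one any_level3 term")
  }
  worst <- 1 - const - sum(dec[, "3"]) - n3
  structure(
    list(constant = const, decrements = dec, n3 = n3,
         range = c(worst, 1), dimensions = dims, source = header),
    class = "eq5d_value_set"
  )
}

#' Score EQ-5D-3L profiles to utilities
#'
#' Applies an additive-decrement tariff: full health scores 1; any departure
#' subtracts the constant term, the per-dimension level decrements, and (for
#' the UK tariff) a further penalty if any dimension is at level 3.
#'
#' @param profile An integer vector of 5 levels (each in 1:3), or a matrix /
#'   data frame with 5 columns of levels, one row per profile.
#' @param value_set An `eq5d_value_set`; defaults to the packaged UK tariff.
#' @return A numeric utility (vector), in `value_set$range`.
#' @examples
#' eq5d_utility(c(1, 1, 1, 1, 1)) # 1
#' eq5d_utility(c(3, 3, 3, 3, 3)) # -0.594 under the UK tariff
#' @export
eq5d_utility <- function(profile, value_set = eq5d_value_set()) {
  stopifnot(inherits(value_set, "eq5d_value_set"))
  m <- if (is.matrix(profile) || is.data.frame(profile)) {
    as.matrix(profile)
  } else {
    matrix(as.numeric(profile), nrow = 1L)
  }
  if (ncol(m) != 5L) {
    abort("an EQ-5D-3L profile has exactly 5 dimension levels")
  }
  if (anyNA(m) || !all(m %in% c(1, 2, 3))) {
    abort("EQ-5D-3L levels must all be in {1, 2, 3}")
  }
  dec <- value_set$decrements
  u <- vapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ]
    if (all(p == 1)) return(1)
    d <- sum(vapply(1:5, function(j) {
      if (p[j] == 1) 0 else dec[j, as.character(p[j])]
    }, numeric(1)))
    1 - value_set$constant - d - if (any(p == 3)) value_set$n3 else 0
  }, numeric(1))
  unname(u)
}

#' All 243 EQ-5D-3L profiles with their tariff utilities
#'
#' @param value_set An `eq5d_value_set`.
#' @return A tibble with the five level columns, a compact `state` label
#'   (e.g. "11223"), and `utility`.
#' @export
eq5d_profiles <- function(value_set = eq5d_value_set()) {
  grid <- expand.grid(
    mobility = 1:3, selfcare = 1:3, usual_activities = 1:3,
    pain_discomfort = 1:3, anxiety_depression = 1:3,
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[order(grid$mobility, grid$selfcare, grid$usual_activities,
                     grid$pain_discomfort, grid$anxiety_depression), ]
  u <- eq5d_utility(grid, value_set)
  tibble::as_tibble(grid) |>
    dplyr::mutate(
      state = paste0(.data$mobility, .data$selfcare, .data$usual_activities,
                     .data$pain_discomfort, .data$anxiety_depression),
      utility = u
    )
}
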