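# Core model objects: metabolites, strains, ecologies, viability and the
# growth-rate model R_i(E, S).
#
# Canonical orders used throughout the package (and in every mask/vector):
#   metabolites ADE < TRP < HIS < LYS
#   strains     ADE, TRP, HIS, LYS  (strain "X" is the X overproducer X-up,
#                                    which requires the other three metabolites)

METABOLITES <- c("ADE", "TRP", "HIS", "LYS")
STRAINS <- c("ADE", "TRP", "HIS", "LYS")

#' Metabolite and strain labels
#'
#' The system has four essential metabolites -- adenine (ADE), tryptophan
#' (TRP), histidine (HIS) and lysine (LYS) -- and four engineered strains,
#' each overproducing exactly one of them while requiring the other three
#' (auxotrophies rescued by the ecology or by cross-feeding partners).
#' Strains are labelled by the metabolite they overproduce.
#'
#' @return Character vector of length 4, in canonical order.
#' @export
metabolites <- function() METABOLITES

#' @rdname metabolites
#' @export
strains <- function() STRAINS

#' Metabolite produced / required by a strain
#'
#' @param strain One of `strains()`.
#' @return `strain_produces()`: the single overproduced metabolite;
#'   `strain_requires()`: the three foreign metabolites the strain cannot
#'   synthesize.
#' @export
strain_produces <- function(strain) {
  match.arg(strain, STRAINS)
}

#' @rdname strain_produces
#' @export
strain_requires <- function(strain) {
  strain <- match.arg(strain, STRAINS)
  setdiff(METABOLITES, strain)
}

#' Enumerate the 16 metabolite ecologies
#'
#' An ecology is the presence/absence state of the four metabolites in a
#' well. The canonical index 1..16 orders ecologies by ascending richness
#' (number of metabolites present), ties broken by ascending binary value
#' with ADE as the most significant bit. Index 1 is the barren ecology
#' (0,0,0,0), index 16 the rich one (1,1,1,1), and index 14 is (1,1,0,1) --
#' the two ecologies 14 and 16 are exactly the ones permissive for a HIS-up
#' monoculture.
#'
#' @return A `data.frame` with columns `index`, `ADE`, `TRP`, `HIS`, `LYS`
#'   (0/1) and `richness`, one row per ecology in canonical order.
#' @export
enumerate_ecologies <- function() {
  if (is.null(.pw$ecologies)) {
    g <- expand.grid(LYS = 0:1, HIS = 0:1, TRP = 0:1, ADE = 0:1,
                     KEEP.OUT.ATTRS = FALSE)
    g <- as.matrix(g[, METABOLITES])
    val <- drop(g %*% c(8L, 4L, 2L, 1L)) # ADE = most significant bit
    g <- g[order(rowSums(g), val), , drop = FALSE]
    rownames(g) <- NULL
    .pw$eco_mat <- g
    # lookup: binary value (0..15) -> canonical index
    v <- drop(g %*% c(8L, 4L, 2L, 1L))
    lut <- integer(16L)
    lut[v + 1L] <- seq_len(16L)
    .pw$val_to_index <- lut
    .pw$ecologies <- data.frame(index = seq_len(16L), g,
                                richness = rowSums(g), row.names = NULL)
  }
  .pw$ecologies
}

#' Ecology index/presence conversions
#'
#' @param index Canonical ecology index in 1..16.
#' @param presence Named or unnamed 0/1 vector of length 4 in canonical
#'   metabolite order.
#' @return `ecology_presence()` returns the named 0/1 presence vector;
#'   `ecology_index()` the canonical index.
#' @export
ecology_presence <- function(index) {
  enumerate_ecologies()
  if (length(index) != 1L || is.na(index) || index != as.integer(index) ||
      index < 1L || index > 16L) {
    stop("`index` must be a single integer in 1..16", call. = FALSE)
  }
  setNames(as.integer(.pw$eco_mat[as.integer(index), ]), METABOLITES)
}

#' @rdname ecology_presence
#' @export
ecology_index <- function(presence) {
  enumerate_ecologies()
  presence <- as_presence(presence)
  val <- sum(presence * c(8L, 4L, 2L, 1L))
  .pw$val_to_index[val + 1L]
}

# coerce/validate an ecology given as index or presence vector
as_presence <- function(ecology) {
  if (length(ecology) == 1L) {
    return(ecology_presence(ecology))
  }
  if (length(ecology) != 4L || anyNA(ecology) || !all(ecology %in% c(0, 1))) {
    stop("an ecology must be a canonical index (1..16) or a 0/1 vector of length 4",
         call. = FALSE)
  }
  setNames(as.integer(ecology), METABOLITES)
}

# validate a community membership (character vector of strain labels)
as_members <- function(community) {
  if (length(community) == 0L) return(character(0))
  community <- as.character(community)
  bad <- setdiff(community, STRAINS)
  if (length(bad)) {
    stop("unknown strain(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unique(community)
}

#' Membership bitmask for a community
#'
#' Four-character 0/1 string in canonical strain order (ADE, TRP, HIS, LYS),
#' e.g. `"1010"` for {ADE-up, HIS-up}.
#'
#' @param community Character vector of strain labels (see [strains()]).
#' @return A 4-character string.
#' @export
membership_mask <- function(community) {
  community <- as_members(community)
  paste0(as.integer(STRAINS %in% community), collapse = "")
}

mask_to_members <- function(mask) {
  if (!is.character(mask) || length(mask) != 1L || nchar(mask) != 4L ||
      grepl("[^01]", mask)) {
    stop("membership mask must be a 4-character 0/1 string", call. = FALSE)
  }
  STRAINS[strsplit(mask, "")[[1]] == "1"]
}

#' Source of a metabolite in a well
#'
#' A metabolite required by a strain can be supplied by the ecology, by a
#' cross-feeding overproducer in the community, or by neither. When both the
#' ecology and a producer are present the ecology shadows cross-feeding (the
#' supplemented growth regime applies).
#'
#' @param ecology Canonical index (1..16) or 0/1 presence vector.
#' @param community Character vector of strain labels present in the well.
#' @param metabolite One of `metabolites()`.
#' @return `"ECOLOGY"`, `"CROSSFED"` or `"ABSENT"`.
#' @export
metabolite_source <- function(ecology, community, metabolite) {
  presence <- as_presence(ecology)
  community <- as_members(community)
  metabolite <- match.arg(metabolite, METABOLITES)
  if (presence[[metabolite]] == 1L) return("ECOLOGY")
  if (metabolite %in% community) return("CROSSFED")
  "ABSENT"
}

#' Community viability in an ecology
#'
#' A community is viable in an ecology if and only if every member strain can
#' obtain all three of its required foreign metabolites, either from the
#' ecology or from a co-inoculated overproducer. Viability is all-or-nothing:
#' one starving member dooms the whole well (all members then share the
#' death rate). The empty community is non-viable by definition.
#'
#' @inheritParams metabolite_source
#' @return Logical scalar.
#' @export
viable <- function(ecology, community) {
  presence <- as_presence(ecology)
  community <- as_members(community)
  if (length(community) == 0L) return(FALSE)
  # a metabolite is available if in the ecology or produced by a member
  available <- presence == 1L | METABOLITES %in% community
  # every member requires the three foreign metabolites, so the community is
  # viable iff every metabolite required by at least one member is available;
  # member i's own product is free to itself.
  for (s in community) {
    if (!all(available[strain_requires(s)])) return(FALSE)
  }
  TRUE
}

#' Growth-rate model parameters
#'
#' The per-strain growth rate in a viable well is parametric:
#' `base_rate(i) * crossfeed_factor^(number of required metabolites obtained
#' only by cross-feeding)`, i.e. each cross-fed (rather than supplemented)
#' requirement discounts the rate by one factor. Explicit overrides --
#' (ecology index, membership mask, strain) -> rate -- take precedence over
#' the parametric rule and carry measured rates. In a non-viable well every
#' member grows at the death rate `death_rate` (< 0). `pool_rates` are the
#' exponential growth rates in the minimal-medium pool phase.
#'
#' Defaults calibrate the parametric rule to the shipped override for the
#' barren ecology with all four strains, whose rates are
#' (0.804, 0.869, 1.157, 0.732) for (ADE, TRP, HIS, LYS): `base_rates` are
#' that vector divided by `crossfeed_factor^3` (all three requirements are
#' cross-fed there), and `pool_rates` default to the same vector.
#'
#' @param base_rates Named or positional numeric vector of 4 positive rates
#'   (1/time), strain order ADE, TRP, HIS, LYS.
#' @param crossfeed_factor Dimensionless multiplier in (0, 1] applied per
#'   cross-fed requirement.
#' @param death_rate Negative rate applied to every member of a non-viable
#'   community (default -2).
#' @param pool_rates Positive per-strain exponential rates for the pool phase.
#' @param overrides `data.frame` with columns `ecology_index`,
#'   `membership_mask`, `strain`, `rate` (see [read_growth_table()]), or
#'   `NULL` for none.
#' @return An object of class `pw_growth_params`.
#' @export
growth_params <- function(base_rates = NULL,
                          crossfeed_factor = 0.95,
                          death_rate = -2,
                          pool_rates = NULL,
                          overrides = default_overrides()) {
  printed <- c(ADE = 0.804, TRP = 0.869, HIS = 1.157, LYS = 0.732)
  check_num1 <- function(x, nm, lo = -Inf, hi = Inf, lo_strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (lo_strict) x <= lo else x < lo) || x > hi) {
      stop(sprintf("`%s` must be a single number in (%s, %s]", nm, lo, hi),
           call. = FALSE)
    }
  }
  check_num1(crossfeed_factor, "crossfeed_factor", lo = 0, hi = 1)
  if (!is.numeric(death_rate) || length(death_rate) != 1L ||
      is.na(death_rate) || death_rate >= 0) {
    stop("`death_rate` must be a single negative number", call. = FALSE)
  }
  if (is.null(base_rates)) base_rates <- printed / crossfeed_factor^3
  if (is.null(pool_rates)) pool_rates <- printed
  fix4 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 4L || anyNA(x) || any(x <= 0)) {
      stop(sprintf("`%s` must be 4 positive numbers", nm), call. = FALSE)
    }
    if (!is.null(names(x))) {
      if (!setequal(names(x), STRAINS)) {
        stop(sprintf("names of `%s` must be %s", nm,
                     paste(STRAINS, collapse = ", ")), call. = FALSE)
      }
      x <- x[STRAINS]
    } else {
      names(x) <- STRAINS
    }
    x
  }
  base_rates <- fix4(base_rates, "base_rates")
  pool_rates <- fix4(pool_rates, "pool_rates")
  overrides <- validate_overrides(overrides)
  structure(
    list(base_rates = base_rates, crossfeed_factor = crossfeed_factor,
         death_rate = death_rate, pool_rates = pool_rates,
         overrides = overrides),
    class = "pw_growth_params"
  )
}

#' Default growth-rate overrides
#'
#' The shipped override table: in the barren ecology (index 1) with all four
#' strains present, the rates are the measured vector
#' (0.804, 0.869, 1.157, 0.732) for (ADE, TRP, HIS, LYS). The same table is
#' installed as a CSV at `system.file("extdata", "default_growth_table.csv",
#' package = "poolwell")`.
#'
#' @return A `data.frame` with columns `ecology_index`, `membership_mask`,
#'   `strain`, `rate`.
#' @export
default_overrides <- function() {
  data.frame(
    ecology_index = 1L,
    membership_mask = "1111",
    strain = STRAINS,
    rate = c(0.804, 0.869, 1.157, 0.732),
    stringsAsFactors = FALSE
  )
}

validate_overrides <- function(overrides) {
  if (is.null(overrides)) {
    return(data.frame(ecology_index = integer(0),
                      membership_mask = character(0),
                      strain = character(0), rate = numeric(0),
                      stringsAsFactors = FALSE))
  }
  need <- c("ecology_index", "membership_mask", "strain", "rate")
  if (!is.data.frame(overrides) || !all(need %in% names(overrides))) {
    stop("overrides must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  overrides <- overrides[, need]
  if (nrow(overrides) == 0L) return(overrides)
  overrides$ecology_index <- as.integer(overrides$ecology_index)
  if (anyNA(overrides$ecology_index) ||
      any(overrides$ecology_index < 1L | overrides$ecology_index > 16L)) {
    stop("override `ecology_index` entries must be integers in 1..16",
         call. = FALSE)
  }
  bad <- nchar(overrides$membership_mask) != 4L |
    grepl("[^01]", overrides$membership_mask)
  if (any(bad)) {
    stop("override membership masks must be 4-character 0/1 strings (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  bad <- !overrides$strain %in% STRAINS
  if (any(bad)) {
    stop("override rows reference unknown strains (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  # the strain must be a member of the community the override describes
  member <- mapply(function(mask, s) substr(mask, match(s, STRAINS),
                                            match(s, STRAINS)) == "1",
                   overrides$membership_mask, overrides$strain)
  if (any(!member)) {
    stop("override rows name strains absent from their membership mask (rows ",
         paste(which(!member), collapse = ", "), ")", call. = FALSE)
  }
  if (!is.numeric(overrides$rate) || anyNA(overrides$rate)) {
    stop("override rates must be numeric", call. = FALSE)
  }
  key <- paste(overrides$ecology_index, overrides$membership_mask,
               overrides$strain)
  if (anyDuplicated(key)) {
    stop("duplicate override keys (ecology_index, membership_mask, strain): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  rownames(overrides) <- NULL
  overrides
}

#' Per-strain growth rates R_i(E, S)
#'
#' In a non-viable (ecology, community) pairing every member's rate is the
#' death rate. In a viable one, each member's rate comes from an override
#' entry if one matches (ecology index, membership mask, strain), otherwise
#' from the parametric rule `base_rate * crossfeed_factor^(#cross-fed
#' requirements)`. Rates are returned only for members.
#'
#' @inheritParams metabolite_source
#' @param params A [growth_params()] object.
#' @return Named numeric vector, one rate per member of `community`, in
#'   canonical strain order.
#' @export
growth_rates <- function(ecology, community, params = growth_params()) {
  stopifnot(inherits(params, "pw_growth_params"))
  presence <- as_presence(ecology)
  community <- as_members(community)
  if (length(community) == 0L) return(setNames(numeric(0), character(0)))
  community <- STRAINS[STRAINS %in% community]
  if (!viable(presence, community)) {
    return(setNames(rep(params$death_rate, length(community)), community))
  }
  idx <- ecology_index(presence)
  mask <- membership_mask(community)
  ov <- params$overrides
  rates <- vapply(community, function(s) {
    hit <- which(ov$ecology_index == idx & ov$membership_mask == mask &
                   ov$strain == s)
    if (length(hit)) return(ov$rate[hit])
    n_crossfed <- sum(vapply(strain_requires(s), function(m) {
      metabolite_source(presence, community, m) == "CROSSFED"
    }, logical(1)))
    params$base_rates[[s]] * params$crossfeed_factor^n_crossfed
  }, numeric(1))
  setNames(rates, community)
}

# Precompute rate and viability lookup tables over all (ecology, membership)
# pairs. Membership id = 8*ADE + 4*TRP + 2*HIS + 1*LYS in 1..15 (non-empty).
# rates: array [16 ecologies, 15 memberships, 4 strains], non-members NA.
rate_tables <- function(params) {
  rates <- array(NA_real_, dim = c(16L, 15L, 4L),
                 dimnames = list(NULL, NULL, STRAINS))
  viab <- matrix(FALSE, 16L, 15L)
  for (m in 1:15) {
    members <- STRAINS[bitwAnd(m, c(8L, 4L, 2L, 1L)) > 0L]
    for (e in 1:16) {
      viab[e, m] <- viable(e, members)
      rates[e, m, members] <- growth_rates(e, members, params)
    }
  }
  list(rates = rates, viable = viab)
}

members_mask_value <- function(community) {
  sum(c(8L, 4L, 2L, 1L)[STRAINS %in% as_members(community)])
}

#' @export
print.pw_growth_params <- function(x, ...) {
  cat("Growth-rate model (4-strain cross-feeding system)\n")
  cat("  base rates      :", paste(sprintf("%s=%.4g", STRAINS, x$base_rates),
                                   collapse = "  "), "\n")
  cat("  crossfeed factor:", x$crossfeed_factor, "\n")
  cat("  death rate d    :", x$death_rate, "\n")
  cat("  pool rates      :", paste(sprintf("%s=%.4g", STRAINS, x$pool_rates),
                                   collapse = "  "), "\n")
  cat("  overrides       :", nrow(x$overrides), "entr",
      if (nrow(x$overrides) == 1) "y" else "ies", "\n", sep = " ")
  invisible(x)
}
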