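# Feeding capacity at swarm landing sites: land-cover aggregation,
# length-of-stay classification and swarm consumption arithmetic.

the_stay_table <- new.env(parent = emptyenv())

#' Land-cover group of a CLC100 code
#'
#' Aggregates Copernicus CLC100 land-cover codes into the five groups used
#' by the stay rules: bare/sparse vegetation -> SPARSE; shrubs, herbaceous
#' vegetation and herbaceous wetland -> SHRUBS; cultivated -> CROPLAND;
#' the 5 closed-forest and 6 open-forest classes -> FOREST; urban, water,
#' snow/ice, moss/lichen and open sea -> NONVEGETATED.
#'
#' @param clc_code Integer CLC100 code(s).
#' @return Character vector of group names.
#' @export
land_group <- function(clc_code) {
  map <- land_group_table()
  idx <- match(clc_code, map$code)
  if (anyNA(idx))
    stop("unknown CLC100 code(s): ",
         paste(unique(clc_code[is.na(idx)]), collapse = ", "))
  map$group[idx]
}

#' @rdname land_group
#' @export
land_group_table <- function() {
  utils::read.csv(system.file("extdata", "clc100_groups.csv",
                              package = "locustsim"),
                  stringsAsFactors = FALSE)
}

#' Length-of-stay class at a landing site
#'
#' Deterministic rule table mapping (land-cover group, vegetation state,
#' NDVI trend) to a stay class: OVERNIGHT (no feeding, depart next
#' morning), SHORT (1-2 days), MEDIUM (2-4 days) or LONG (4-7 days).
#' The table satisfies: NOVEG state or NONVEGETATED group always gives
#' OVERNIGHT; LONG occurs only on cropland with higher/highest vegetation
#' density under an increasing or constant trend; the class is monotone
#' non-decreasing in vegetation state and never larger under a decreasing
#' than an increasing trend; sparse vegetation never exceeds SHORT. The
#' full 90-row table ships as a reviewable CSV resource
#' (`stay_class_table()`).
#'
#' @param group Land-cover group (see [land_group()]).
#' @param state Vegetation state (see [veg_state()]).
#' @param trend Trend state: "INCREASING", "CONSTANT" or "DECREASING".
#' @return Character stay class, vectorised over the inputs.
#' @examples
#' stay_class("CROPLAND", "HIGHER", "INCREASING")  # "LONG"
#' @export
stay_class <- function(group, state, trend) {
  tab <- stay_class_table()
  key <- paste(group, state, trend, sep = "|")
  idx <- match(key, paste(tab$group, tab$state, tab$trend, sep = "|"))
  if (anyNA(idx)) stop("invalid (group, state, trend) combination")
  tab$class[idx]
}

#' @rdname stay_class
#' @export
stay_class_table <- function() {
  if (is.null(the_stay_table$tab)) {
    the_stay_table$tab <- utils::read.csv(
      system.file("extdata", "stay_classes.csv", package = "locustsim"),
      stringsAsFactors = FALSE)
  }
  the_stay_table$tab
}

#' Feeding-day ranges of the stay classes
#'
#' @return Named list of closed integer ranges: OVERNIGHT 0 days, SHORT
#'   1-2, MEDIUM 2-4, LONG 4-7.
#' @export
stay_class_ranges <- function() {
  list(OVERNIGHT = c(0L, 0L), SHORT = c(1L, 2L),
       MEDIUM = c(2L, 4L), LONG = c(4L, 7L))
}

#' Sample a stay duration
#'
#' Draws the number of feeding days uniformly from the closed integer range
#' of the class (OVERNIGHT feeds 0 days and departs the next morning).
#' Uses the current RNG stream.
#'
#' @param cls Stay class name.
#' @return Integer feeding days.
#' @export
sample_stay_days <- function(cls) {
  rg <- stay_class_ranges()[[cls]]
  if (is.null(rg)) stop("unknown stay class: ", cls)
  if (rg[1L] == rg[2L]) return(rg[1L])
  sample(rg[1L]:rg[2L], 1L)
}

#' Daily food requirement of a swarm
#'
#' Plant material consumed per square kilometre per day, from swarm density
#' and per-locust intake: density * intake / 1e6 tonnes. At the literature
#' density range 3.5e7-5e7 locusts/km^2 and 2 g/day intake this gives the
#' familiar 70-100 t/km^2/day.
#'
#' @param density_per_km2 Locusts per km^2.
#' @param intake_g_per_day Grams eaten per locust per day (default 2.0;
#'   literature range 1.0-5.0).
#' @return Tonnes of plant material per km^2 per day.
#' @examples
#' swarm_food_requirement(3.5e7, 2)  # 70
#' @export
swarm_food_requirement <- function(density_per_km2, intake_g_per_day = 2.0) {
  stopifnot(all(density_per_km2 >= 0), all(intake_g_per_day >= 0))
  density_per_km2 * intake_g_per_day / 1e6
}
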