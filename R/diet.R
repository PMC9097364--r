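# Diet-category engine over EltonTraits-style percentage rows.
#
# A taxon's diet is a percentage breakdown over food categories; it is
# assigned to a specialist category when the relevant percentage meets the
# category's cut-off, at either the standard (strict) or semi-specialist
# (relaxed) level.  Mechanical subdivisions (hard/soft fruit, husking/
# swallowing granivory, hard/medium/soft invertebrates) are resolved from
# annotations, not percentages.

#' The 13 diet categories used throughout the pipeline
#' @return Character vector of category names.
#' @export
diet_categories <- function() {
  c("Folivore", "FrugivoreH", "FrugivoreS", "Generalist", "GranivoreH",
    "GranivoreS", "InvertivoreH", "InvertivoreM", "InvertivoreS",
    "Nectarivore", "Piscivore", "Scavenger", "TetrapodHunter")
}

#' Inclusive roll-up of a diet category
#' @param category Diet category name(s).
#' @return `"Carnivore"`, `"Herbivore"` or `"Omnivore"` per element.
#' @export
diet_rollup <- function(category) {
  carn <- c("InvertivoreH", "InvertivoreM", "InvertivoreS", "Piscivore",
            "Scavenger", "TetrapodHunter")
  herb <- c("Folivore", "FrugivoreH", "FrugivoreS", "GranivoreH",
            "GranivoreS", "Nectarivore")
  ifelse(category %in% carn, "Carnivore",
         ifelse(category %in% herb, "Herbivore", "Omnivore"))
}

#' Vertivore categories (vertebrate-eating carnivores)
#' @return Character vector.
#' @export
vertivore_categories <- function() c("Piscivore", "Scavenger", "TetrapodHunter")

#' Load the diet cut-off table
#'
#' The cut-offs ship as JSON in `inst/extdata/diet_cutoffs.json` so they can
#' be inspected or modified; each entry gives the diet column tested, the
#' standard threshold and the semi-specialist threshold (percent of diet,
#' read inclusively as ">=").
#'
#' @param path Optional path to an alternative JSON cut-off file.
#' @return Data frame with columns diet, column, standard, semi.
#' @export
diet_cutoffs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "diet_cutoffs.json", package = "aviandiet")
  df <- jsonlite::fromJSON(path)
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Construct a diet percentage profile
#'
#' @param Inv,Ect,End,Vunk,Fish,Scav,Fruit,Nect,Seed,PlantO Percentages of
#'   the diet (0-100); must sum to 100 within 0.5.
#' @param fruit_hardness `"hard"` or `"soft"` (optional annotation).
#' @param granivory_mode `"husk"` or `"swallow"` (optional).
#' @param invert_hardness `"hard"`, `"medium"` or `"soft"` (optional).
#' @param scavenger_note Free-text note (e.g. kleptoparasitism).
#' @return Object of class `diet_profile`.
#' @export
diet_profile <- function(Inv = 0, Ect = 0, End = 0, Vunk = 0, Fish = 0,
                         Scav = 0, Fruit = 0, Nect = 0, Seed = 0, PlantO = 0,
                         fruit_hardness = NULL, granivory_mode = NULL,
                         invert_hardness = NULL, scavenger_note = NULL) {
  p <- c(Inv = Inv, Ect = Ect, End = End, Vunk = Vunk, Fish = Fish,
         Scav = Scav, Fruit = Fruit, Nect = Nect, Seed = Seed,
         PlantO = PlantO)
  if (any(p < 0 | p > 100)) stop("percentages must lie in [0, 100]")
  if (abs(sum(p) - 100) > 0.5)
    stop(sprintf("percentages sum to %.2f, not 100", sum(p)))
  structure(list(pct = p, fruit_hardness = fruit_hardness,
                 granivory_mode = granivory_mode,
                 invert_hardness = invert_hardness,
                 scavenger_note = scavenger_note),
            class = "diet_profile")
}

#' Preprocess a diet profile: tetrapod merge and unknown-vertebrate split
#'
#' Ectothermic and endothermic tetrapod percentages are merged into a single
#' `Tetr` component (hunting requirements do not differ), and the unknown
#' vertebrate component is split evenly between `Fish` and `Tetr`.
#'
#' @param p A [diet_profile()].
#' @return A `diet_profile` whose `pct` gains `Tetr` and zeroes `Ect`,
#'   `End`, `Vunk`.
#' @export
preprocess_profile <- function(p) {
  stopifnot(inherits(p, "diet_profile"))
  q <- p$pct
  tetr <- q[["Ect"]] + q[["End"]] + q[["Vunk"]] / 2
  fish <- q[["Fish"]] + q[["Vunk"]] / 2
  q[c("Ect", "End", "Vunk")] <- 0
  q[["Fish"]] <- fish
  p$pct <- c(q, Tetr = tetr)
  p$preprocessed <- TRUE
  p
}

resolve_subcategory <- function(diet, p) {
  switch(diet,
    Invertivore = {
      h <- p$invert_hardness
      if (is.null(h)) stop("invertivore requires an invert_hardness annotation")
      c(hard = "InvertivoreH", medium = "InvertivoreM",
        soft = "InvertivoreS")[[match.arg(h, c("hard", "medium", "soft"))]]
    },
    Frugivore = {
      h <- p$fruit_hardness
      if (is.null(h)) stop("frugivore requires a fruit_hardness annotation")
      c(hard = "FrugivoreH", soft = "FrugivoreS")[[match.arg(h, c("hard", "soft"))]]
    },
    Granivore = {
      m <- p$granivory_mode
      if (is.null(m)) stop("granivore requires a granivory_mode annotation")
      c(husk = "GranivoreH", swallow = "GranivoreS")[[match.arg(m, c("husk", "swallow"))]]
    },
    TetrapodHunter = "TetrapodHunter",
    diet)
}

#' Classify a diet profile into a diet category
#'
#' Applies the cut-off table to a preprocessed profile.  Standard cut-offs
#' are tried first; with `include_semi = TRUE` the relaxed semi-specialist
#' cut-offs are then tried for profiles not classified at the standard
#' level.  A profile with no category above 30% (standard) or 40% (semi) is
#' a Generalist.  Returns `NA` (unclassified) when no rule fires.
#'
#' @param p Preprocessed [diet_profile()] (see [preprocess_profile()]).
#' @param include_semi Also apply semi-specialist cut-offs.
#' @param cutoffs Cut-off table from [diet_cutoffs()].
#' @return List with `category` (or `NA`), `specialist_level`
#'   (`"standard"`/`"semi"`/`NA`).
#' @export
classify_diet <- function(p, include_semi = FALSE, cutoffs = diet_cutoffs()) {
  stopifnot(inherits(p, "diet_profile"))
  if (!isTRUE(p$preprocessed)) p <- preprocess_profile(p)
  q <- p$pct
  spec <- cutoffs[cutoffs$diet != "Generalist", ]
  level_hit <- function(thresholds) {
    hits <- spec$diet[q[spec$column] >= thresholds]
    hits[!is.na(hits)]
  }
  hits <- level_hit(spec$standard)
  if (length(hits) > 1L)
    stop("ambiguous classification; cut-offs fired for: ",
         paste(hits, collapse = ", "))
  if (length(hits) == 1L)
    return(list(category = resolve_subcategory(hits, p),
                specialist_level = "standard"))
  gen_row <- cutoffs[cutoffs$diet == "Generalist", ]
  # Generalist: no single food category dominates
  food <- q[c("Inv", "Fish", "Scav", "Fruit", "Nect", "Seed", "PlantO", "Tetr")]
  if (max(food) <= gen_row$standard)
    return(list(category = "Generalist", specialist_level = "standard"))
  if (include_semi) {
    hits <- level_hit(spec$semi)
    if (length(hits) > 1L)
      stop("ambiguous semi-specialist classification; cut-offs fired for: ",
           paste(hits, collapse = ", "))
    if (length(hits) == 1L)
      return(list(category = resolve_subcategory(hits, p),
                  specialist_level = "semi"))
    if (max(food) <= gen_row$semi)
      return(list(category = "Generalist", specialist_level = "semi"))
  }
  list(category = NA_character_, specialist_level = NA_character_)
}
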