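#' Validate a cell-annotation table for tracing quantification
#'
#' One record per labeled neuron from a monosynaptic rabies-tracing
#' experiment: animal, class (`starter` = helper + rabies co-infected seed
#' neuron; `input` = rabies-only presynaptic neuron), atlas region acronym
#' and hemisphere (`ipsi`/`contra` relative to the injection).
#'
#' @param table data.frame with columns `animal_id`, `cell_id`, `class`,
#'   `region_acronym`, `hemisphere`.
#' @param atlas_acronyms character vector of valid region acronyms; when
#'   supplied, unknown acronyms are an error.
#' @return the validated data.frame (invisibly unchanged), with factors
#'   normalized to character.
#' @export
validate_annotations <- function(table, atlas_acronyms = NULL) {
  req <- c("animal_id", "cell_id", "class", "region_acronym", "hemisphere")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  table[req] <- lapply(table[req], as.character)
  bad_class <- setdiff(unique(table$class), c("starter", "input"))
  if (length(bad_class))
    stop("unknown class value(s): ", paste(bad_class, collapse = ", "))
  if (nrow(table) &&
      anyDuplicated(paste(table$animal_id, table$cell_id, sep = "\r")))
    stop("cell_id values must be unique within each animal")
  if (!is.null(atlas_acronyms)) {
    unknown <- setdiff(unique(table$region_acronym), atlas_acronyms)
    if (length(unknown))
      stop("region acronym(s) not in the atlas list: ",
           paste(unknown, collapse = ", "))
  }
  table
}

#' Count input neurons per animal and brain region
#'
#' Starter (seed) neurons are excluded: only `input`-class cells are
#' counted.
#'
#' @param table annotation data.frame (see [validate_annotations()]).
#' @param atlas_acronyms optional acronym whitelist, passed through to
#'   validation.
#' @return data.frame with columns `animal_id`, `region_acronym`, `count`.
#' @export
tabulate_regions <- function(table, atlas_acronyms = NULL) {
  table <- validate_annotations(table, atlas_acronyms)
  inputs <- table[table$class == "input", , drop = FALSE]
  if (!nrow(inputs))
    return(data.frame(animal_id = character(0), region_acronym = character(0),
                      count = integer(0)))
  counts <- stats::aggregate(list(count = rep(1L, nrow(inputs))),
                             by = inputs[c("animal_id", "region_acronym")],
                             FUN = sum)
  counts[order(counts$animal_id, counts$region_acronym), , drop = FALSE]
}

# internal: standard error of the mean across animals; NA for n = 1
# (a single animal has no between-animal spread, reported as absent)
sem <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))

#' Pool per-animal region fractions into a summary
#'
#' Each animal's counts are first normalized to percentages of its own
#' input total (so animals with different labeling totals weigh equally),
#' then pooled as the unweighted mean across animals with the SEM across
#' animals. Regions whose pooled mean falls below `min_percent` are flagged
#' as excluded from display (the convention for the published bar graphs)
#' but are retained in the full table - the cutoff never alters totals.
#'
#' @param counts output of [tabulate_regions()].
#' @param min_percent display cutoff in percent (default 0.3).
#' @param mode `"per_animal"` (default): pooled value = mean of per-animal
#'   percentages; `"pooled"`: percentages of the summed counts across
#'   animals (selectable for comparison; SEM is not defined in this mode).
#' @return list of class `region_input_summary` with elements
#'   `per_animal_pct` (data.frame animal x region percent), `summary`
#'   (data.frame: `region_acronym`, `mean_pct`, `sem_pct`,
#'   `display_excluded`), `totals` (n_inputs, n_animals).
#' @export
pool_fractions <- function(counts, min_percent = 0.3,
                           mode = c("per_animal", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(counts), all(c("animal_id", "region_acronym", "count")
                                       %in% names(counts)))
  totals <- tapply(counts$count, counts$animal_id, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    warning("animal(s) with zero inputs excluded: ", paste(zero, collapse = ", "))
    counts <- counts[!counts$animal_id %in% zero, , drop = FALSE]
    totals <- totals[!names(totals) %in% zero]
  }
  if (!length(totals)) stop("no animal with at least one input neuron")
  counts$pct <- 100 * counts$count / as.numeric(totals[counts$animal_id])
  regions <- sort(unique(counts$region_acronym))
  animals <- sort(unique(counts$animal_id))
  mat <- matrix(0, length(animals), length(regions),
                dimnames = list(animals, regions))
  mat[cbind(counts$animal_id, counts$region_acronym)] <- counts$pct
  if (mode == "per_animal") {
    mean_pct <- colMeans(mat)
    sem_pct <- apply(mat, 2, sem)
  } else {
    pooled_counts <- tapply(counts$count, counts$region_acronym, sum)[regions]
    mean_pct <- 100 * as.numeric(pooled_counts) / sum(pooled_counts)
    names(mean_pct) <- regions
    sem_pct <- rep(NA_real_, length(regions))
  }
  summary <- data.frame(
    region_acronym = regions,
    mean_pct = as.numeric(mean_pct),
    sem_pct = as.numeric(sem_pct),
    display_excluded = as.numeric(mean_pct) < min_percent,
    row.names = NULL
  )
  summary <- summary[order(-summary$mean_pct), , drop = FALSE]
  structure(
    list(per_animal_pct = as.data.frame(mat), summary = summary,
         totals = list(n_inputs = sum(counts$count),
                       n_animals = length(animals)),
         min_percent = min_percent, mode = mode),
    class = "region_input_summary"
  )
}

#' @export
print.region_input_summary <- function(x, ...) {
  cat(sprintf("<region_input_summary> %d inputs, %d animals (%s)\n",
              x$totals$n_inputs, x$totals$n_animals, x$mode))
  shown <- x$summary[!x$summary$display_excluded, , drop = FALSE]
  print(utils::head(shown, 10), row.names = FALSE)
  nex <- sum(x$summary$display_excluded)
  if (nex) cat(sprintf("(+ %d region(s) below the %.1f%% display cutoff)\n",
                       nex, x$min_percent))
  invisible(x)
}

#' Seeding efficiency: labeled inputs per starter neuron
#'
#' Per-animal ratio of input to starter counts, averaged across animals
#' (mean of per-animal ratios, not the ratio of pooled counts - the two
#' differ whenever labeling totals differ between animals).
#'
#' @param table annotation data.frame.
#' @return list with `per_animal` (data.frame: animal_id, n_inputs,
#'   n_starters, ratio), `mean`, `sem`.
#' @export
seeding_efficiency <- function(table) {
  table <- validate_annotations(table)
  animals <- sort(unique(table$animal_id))
  per <- do.call(rbind, lapply(animals, function(a) {
    sub <- table[table$animal_id == a, ]
    ns <- sum(sub$class == "starter")
    ni <- sum(sub$class == "input")
    if (ns == 0)
      stop(sprintf("animal %s has no starter neurons; efficiency undefined", a))
    data.frame(animal_id = a, n_inputs = ni, n_starters = ns,
               ratio = ni / ns)
  }))
  list(per_animal = per, mean = mean(per$ratio), sem = sem(per$ratio))
}

#' Ipsilateral bias of the input population
#'
#' Per-animal percentage of input neurons on the hemisphere ipsilateral to
#' the injection, averaged across animals.
#'
#' @param table annotation data.frame; every input record must carry a
#'   hemisphere (`ipsi` or `contra`).
#' @return list with `per_animal` (data.frame: animal_id, pct_ipsi),
#'   `mean`, `sem`.
#' @export
laterality_bias <- function(table) {
  table <- validate_annotations(table)
  inputs <- table[table$class == "input", , drop = FALSE]
  bad <- which(!inputs$hemisphere %in% c("ipsi", "contra") |
                 is.na(inputs$hemisphere) | inputs$hemisphere == "")
  if (length(bad))
    stop(sprintf("hemisphere missing or invalid on input record %s (animal %s)",
                 inputs$cell_id[bad[1]], inputs$animal_id[bad[1]]))
  animals <- sort(unique(inputs$animal_id))
  per <- do.call(rbind, lapply(animals, function(a) {
    sub <- inputs[inputs$animal_id == a, ]
    data.frame(animal_id = a,
               pct_ipsi = 100 * mean(sub$hemisphere == "ipsi"))
  }))
  list(per_animal = per, mean = mean(per$pct_ipsi), sem = sem(per$pct_ipsi))
}

#' Simulate a cell-annotation table with known region proportions
#'
#' Draws each animal's input neurons from a multinomial over regions and a
#' Bernoulli hemisphere assignment, plus a fixed number of starter cells in
#' the seed region. Used to validate that the quantification recovers
#' planted proportions.
#'
#' @param n_animals number of animals.
#' @param cells_per_animal input neurons per animal.
#' @param region_probs named numeric vector of region probabilities
#'   (summing to 1).
#' @param ipsi_prob probability that an input lies ipsilateral.
#' @param starters_per_animal starter (seed) cells per animal.
#' @param seed_region acronym holding the starters.
#' @param seed integer RNG seed.
#' @return data.frame in the annotation-table layout.
#' @export
simulate_annotations <- function(n_animals = 3, cells_per_animal = 100,
                                 region_probs = c(IRT = 0.4, GRN = 0.25,
                                                  PARN = 0.15, SC = 0.12,
                                                  MOp = 0.08),
                                 ipsi_prob = 0.556,
                                 starters_per_animal = 10,
                                 seed_region = "IRT", seed = 1L) {
  stopifnot(abs(sum(region_probs) - 1) < 1e-9)
  with_seed(as.integer(seed), {
    rows <- list()
    for (a in seq_len(n_animals)) {
      aid <- sprintf("animal%02d", a)
      counts <- as.integer(stats::rmultinom(1, cells_per_animal, region_probs))
      regions <- rep(names(region_probs), counts)
      hemi <- ifelse(stats::runif(cells_per_animal) < ipsi_prob, "ipsi", "contra")
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = aid,
        cell_id = sprintf("c%04d", seq_len(cells_per_animal)),
        class = "input", region_acronym = regions, hemisphere = hemi)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = aid,
        cell_id = sprintf("s%04d", seq_len(starters_per_animal)),
        class = "starter", region_acronym = seed_region, hemisphere = "ipsi")
    }
    do.call(rbind, rows)
  })
}
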