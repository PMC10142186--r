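# Compositional venom and diet data: containers, readers, cleaning, summaries.

#' Construct a venomic abundance profile
#'
#' One profile represents a single venomic record: the relative abundance of
#' each toxin protein family reported by one proteomic or transcriptomic study
#' for one species.
#'
#' @param species Binomial species name.
#' @param record_id Unique identifier of the venomic record.
#' @param source Study citation key.
#' @param method "proteome" or "transcriptome".
#' @param components Named numeric vector: toxin family -> percent (or
#'   fractional) abundance; names unique, values >= 0.
#' @return An object of class `abundance_profile`. `raw_total_percent` keeps
#'   the reported total before any normalization, for audit.
#' @export
abundance_profile <- function(species, record_id, source, method, components) {
  method <- match.arg(method, c("proteome", "transcriptome"))
  if (is.null(names(components)) || anyDuplicated(names(components)))
    stop("components must have unique toxin-family names")
  if (any(components < 0))
    stop("negative abundance in record ", record_id)
  structure(
    list(species = as.character(species),
         record_id = as.character(record_id),
         source = as.character(source),
         method = method,
         components = components,
         raw_total_percent = sum(components),
         normalized = FALSE),
    class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> %s [%s, %s] %d families, raw total %.1f%%%s\n",
              x$species, x$record_id, x$method, length(x$components),
              x$raw_total_percent,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

.read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}

#' Read venomic composition records from a CSV/TSV file
#'
#' Expects columns `species, record_id, source, method, toxin_family,
#' percent_abundance`, one row per (record, toxin family). Abundances are NOT
#' normalized here; [clean_venom_profiles()] does that after filtering.
#'
#' @param path Path to a comma- or tab-separated table.
#' @return List of [abundance_profile()] objects, one per distinct
#'   (species, record_id).
#' @export
read_venom_profiles <- function(path) {
  df <- .read_table_auto(path)
  needed <- c("species", "record_id", "source", "method",
              "toxin_family", "percent_abundance")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("venom table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  bad <- which(df$percent_abundance < 0)
  if (length(bad))
    stop("negative percent_abundance at row(s): ", paste(bad, collapse = ", "))
  dup <- duplicated(df[, c("record_id", "toxin_family")])
  if (any(dup))
    stop("duplicate (record_id, toxin_family) at row(s): ",
         paste(which(dup), collapse = ", "))
  idx <- split(seq_len(nrow(df)), df$record_id)
  # preserve file order of first appearance
  idx <- idx[order(vapply(idx, min, 1L))]
  lapply(idx, function(i) {
    sub <- df[i, , drop = FALSE]
    if (length(unique(sub$species)) != 1L)
      stop("record ", sub$record_id[1], " spans multiple species")
    comp <- stats::setNames(sub$percent_abundance, sub$toxin_family)
    abundance_profile(sub$species[1], sub$record_id[1], sub$source[1],
                      sub$method[1], comp)
  })
}

#' Clean and normalize venomic profiles
#'
#' Removes records whose reported total percent abundance is implausible:
#' above `max_total_percent` (reason `total_above_cap`) or below
#' `min_total_percent` (reason `total_below_floor`). Survivors are
#' renormalized so components sum to 1; component ratios are preserved.
#'
#' @param profiles List of [abundance_profile()].
#' @param max_total_percent Upper cap on reported totals (default 110,
#'   allowing leeway above 100 for rounding error).
#' @param min_total_percent Lower floor (default 90, symmetric leeway).
#' @return List with `profiles` (retained, normalized) and `report`
#'   (a `cleaning_report` with one reason per removed record).
#' @export
clean_venom_profiles <- function(profiles, max_total_percent = 110,
                                 min_total_percent = 90) {
  tot <- vapply(profiles, function(p) p$raw_total_percent, 1.0)
  above <- tot > max_total_percent
  below <- tot < min_total_percent
  keep <- !(above | below)
  removed_ids <- vapply(profiles[!keep], function(p) p$record_id, "")
  reasons <- ifelse(above[!keep], "total_above_cap", "total_below_floor")
  retained <- lapply(profiles[keep], function(p) {
    p$components <- p$components / sum(p$components)
    p$normalized <- TRUE
    p
  })
  report <- structure(
    list(n_input = length(profiles),
         n_removed_abundance = sum(!keep),
         n_removed_diet = 0L,
         removed_ids = data.frame(id = removed_ids, reason = reasons,
                                  stringsAsFactors = FALSE)),
    class = "cleaning_report")
  list(profiles = retained, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d input, %d removed (venom), %d removed (diet)\n",
              x$n_input, x$n_removed_abundance, x$n_removed_diet))
  if (nrow(x$removed_ids)) print(x$removed_ids)
  invisible(x)
}

#' Read diet records from a CSV/TSV file
#'
#' Expects columns `species, prey_family, prey_order, n_records`.
#'
#' @param path Path to a comma- or tab-separated table.
#' @return data.frame of diet records.
#' @export
read_diet_records <- function(path) {
  df <- .read_table_auto(path)
  needed <- c("species", "prey_family", "prey_order", "n_records")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("diet table is missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Aggregate diet records per species at a taxonomic level
#'
#' Sums prey record counts per species at family or order level. Rows lacking
#' a label at the requested level (NA or empty) are dropped; the number of
#' dropped rows is attached as attribute `n_missing_label`.
#'
#' @param records data.frame with columns `species`, `prey_family`,
#'   `prey_order`, `n_records` (positive integer counts).
#' @param level "family" or "order".
#' @return List of `diet_count_table` objects (one per species), with
#'   attribute `n_missing_label`.
#' @export
aggregate_diet <- function(records, level = c("family", "order")) {
  level <- match.arg(level)
  col <- if (level == "family") "prey_family" else "prey_order"
  if (nrow(records) == 0L) {
    out <- list()
    attr(out, "n_missing_label") <- 0L
    return(out)
  }
  if (any(is.na(records$n_records)) || any(records$n_records <= 0) ||
      any(records$n_records != round(records$n_records)))
    stop("n_records must be positive integers")
  lab <- as.character(records[[col]])
  ok <- !is.na(lab) & nzchar(lab)
  dropped <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  lab <- lab[ok]
  idx <- split(seq_len(nrow(records)), records$species)
  idx <- idx[order(vapply(idx, min, 1L))]  # first-appearance species order
  out <- unname(lapply(idx, function(i) {
    counts <- tapply(records$n_records[i], lab[i], sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
    structure(list(species = records$species[i[1]],
                   level = level,
                   counts = counts,
                   total_records = sum(counts)),
              class = "diet_count_table")
  }))
  attr(out, "n_missing_label") <- dropped
  out
}

#' @export
print.diet_count_table <- function(x, ...) {
  cat(sprintf("<diet_count_table> %s (%s level): %d taxa, %d records\n",
              x$species, x$level, length(x$counts), x$total_records))
  invisible(x)
}

#' Filter out species with too few diet records
#'
#' Species whose pooled prey record count is below `min_items` are removed, so
#' diet diversity is never computed from a handful of possibly unusual
#' records. Applied independently for each taxonomic level.
#'
#' @param tables List of `diet_count_table` (one taxonomic level).
#' @param min_items Minimum total prey records to retain a species
#'   (default 5).
#' @return List with `tables` (retained) and `report` (a `cleaning_report`).
#' @export
filter_diet <- function(tables, min_items = 5) {
  tot <- vapply(tables, function(t) t$total_records, 1L)
  keep <- tot >= min_items
  removed <- vapply(tables[!keep], function(t) t$species, "")
  report <- structure(
    list(n_input = length(tables),
         n_removed_abundance = 0L,
         n_removed_diet = sum(!keep),
         removed_ids = data.frame(
           id = removed,
           reason = rep("too_few_prey_records", length(removed)),
           stringsAsFactors = FALSE)),
    class = "cleaning_report")
  list(tables = tables[keep], report = report)
}

#' Per-record diversity table joining venom and diet
#'
#' Computes Shannon and Gini-Simpson diversity of every venomic record and
#' attaches the (single, species-level) diet diversity at family and order
#' level. Species present in the venom data but in neither diet dataset are
#' dropped and listed in attribute `dropped_species`. Rows carry NA for a
#' level at which the species has no (filtered) diet data; per-level analyses
#' exclude those rows.
#'
#' @param profiles Cleaned, normalized venom profiles.
#' @param diet_family,diet_order Filtered `diet_count_table` lists at family
#'   and order level (either may be an empty list).
#' @return data.frame, one row per venomic record: `record_id`, `species`,
#'   `method`, `venom_shannon`, `venom_simpson`, `diet_shannon_family`,
#'   `diet_simpson_family`, `diet_shannon_order`, `diet_simpson_order`.
#' @export
diversity_table <- function(profiles, diet_family, diet_order) {
  div_of <- function(tables, fun) {
    vals <- vapply(tables, function(t) fun(t$counts / t$total_records), 1.0)
    stats::setNames(vals, vapply(tables, function(t) t$species, ""))
  }
  dsf <- div_of(diet_family, shannon_index)
  dgf <- div_of(diet_family, simpson_index)
  dso <- div_of(diet_order, shannon_index)
  dgo <- div_of(diet_order, simpson_index)
  sp <- vapply(profiles, function(p) p$species, "")
  have_diet <- sp %in% names(dsf) | sp %in% names(dso)
  dropped <- sort(unique(sp[!have_diet]))
  profiles <- profiles[have_diet]
  sp <- sp[have_diet]
  na_lookup <- function(v, key)
    ifelse(key %in% names(v), unname(v[key]), NA_real_)
  out <- data.frame(
    record_id = vapply(profiles, function(p) p$record_id, ""),
    species = sp,
    method = vapply(profiles, function(p) p$method, ""),
    venom_shannon = vapply(profiles, function(p) shannon_index(p$components), 1.0),
    venom_simpson = vapply(profiles, function(p) simpson_index(p$components), 1.0),
    diet_shannon_family = na_lookup(dsf, sp),
    diet_simpson_family = na_lookup(dgf, sp),
    diet_shannon_order = na_lookup(dso, sp),
    diet_simpson_order = na_lookup(dgo, sp),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped_species") <- dropped
  out
}

#' Count distinct prey taxa for one species
#'
#' Tallies the number of distinct prey families and orders in a set of diet
#' records (e.g., to compare taxonomic diet breadth between congeners).
#' Missing labels are ignored per level.
#'
#' @param records data.frame with columns `prey_family` and `prey_order`.
#' @return Named integer vector `c(n_families = , n_orders = )`.
#' @export
count_prey_taxa <- function(records) {
  distinct_nonempty <- function(x) {
    x <- as.character(x)
    length(unique(x[!is.na(x) & nzchar(x)]))
  }
  if (is.null(records) || nrow(records) == 0L)
    return(c(n_families = 0L, n_orders = 0L))
  c(n_families = distinct_nonempty(records$prey_family),
    n_orders = distinct_nonempty(records$prey_order))
}
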