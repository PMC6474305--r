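#' @name data-model
#' @title Input tables and the aligned analysis dataset
#' @description
#' The pipeline consumes three tab-delimited tables: per-quadrat sample
#' metadata (site, region, season, porewater salinity and pH, soil moisture,
#' plant species richness, root biomass, and percentage cover of five plant
#' growth-form groups), an OTU count table (samples x OTUs, integer sequence
#' counts), and an optional guild table mapping OTUs to FUNGuild-style
#' trophic groups. `read_dataset()` validates and aligns them into a single
#' `fungal_dataset` carrying per-sample OTU richness.
NULL

SAMPLE_COLUMNS <- c("sample_id", "site", "region", "season", "salinity",
                    "ph", "moisture", "plant_richness", "root_biomass",
                    "cover_herb", "cover_shrub", "cover_grass",
                    "cover_sedge", "cover_rush")
COVER_COLUMNS <- grep("^cover_", SAMPLE_COLUMNS, value = TRUE)
SEASON_LEVELS <- c("summer", "winter")  # summer is the reference level

#' Default trophic-group label set
#'
#' Three pure trophic modes, the three pairwise combinations, and the
#' distinguished "unassigned" level for OTUs FUNGuild could not place.
#' @export
trophic_groups <- function() {
  c("pathotroph", "saprotroph", "symbiotroph",
    "pathotroph-saprotroph", "pathotroph-symbiotroph",
    "saprotroph-symbiotroph", "unassigned")
}

validate_sample_table <- function(samples) {
  missing <- setdiff(SAMPLE_COLUMNS, names(samples))
  if (length(missing))
    stop("sample table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id values in sample table")
  num_cols <- setdiff(SAMPLE_COLUMNS, c("sample_id", "site", "region", "season"))
  for (cc in SAMPLE_COLUMNS) {
    if (anyNA(samples[[cc]])) stop("missing values in sample column '", cc, "'")
  }
  if (!all(samples$season %in% SEASON_LEVELS))
    stop("season must be one of: ", paste(SEASON_LEVELS, collapse = ", "))
  site_region <- unique(samples[, c("site", "region")])
  if (anyDuplicated(site_region$site))
    stop("each site must map to exactly one region")
  for (cc in COVER_COLUMNS) {
    if (any(samples[[cc]] < 0 | samples[[cc]] > 100))
      stop("'", cc, "' must lie in [0, 100]")
  }
  if (any(samples$ph < 0 | samples$ph > 14)) stop("'ph' must lie in [0, 14]")
  if (any(samples$salinity < 0)) stop("'salinity' must be non-negative")
  if (any(samples$plant_richness < 0) ||
      any(abs(samples$plant_richness - round(samples$plant_richness)) > 1e-8))
    stop("'plant_richness' must be a non-negative integer")
  if (any(samples$root_biomass < 0)) stop("'root_biomass' must be non-negative")
  samples$site <- as.character(samples$site)
  samples$region <- as.character(samples$region)
  samples$season <- as.character(samples$season)
  samples
}

validate_otu_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU count matrix needs sample row names and OTU column names")
  if (anyDuplicated(colnames(counts))) stop("duplicate otu_ids in OTU table")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "negative or non-integer count at sample '%s', OTU '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  if (any(rowSums(counts) == 0))
    stop("sample(s) with zero library size: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  counts
}

#' Per-sample library sizes (OTU-table row sums)
#' @param counts samples x OTUs count matrix.
#' @export
library_sizes <- function(counts) rowSums(counts)

#' Per-sample OTU richness
#'
#' Number of OTUs with a count greater than zero in each sample; the response
#' of the richness models.
#'
#' @param counts samples x OTUs integer count matrix (or a `fungal_dataset`).
#' @return named integer vector, one entry per sample.
#' @export
compute_richness <- function(counts) {
  if (inherits(counts, "fungal_dataset")) counts <- counts$counts
  as.integer(rowSums(counts > 0))
}

#' Construct an aligned analysis dataset
#'
#' @param samples validated sample metadata data.frame.
#' @param counts samples x OTUs integer matrix, row names = sample ids.
#' @param guilds optional data.frame with columns `otu_id`, `trophic_group`;
#'   OTUs it does not list are labelled "unassigned".
#' @return object of class `fungal_dataset` with elements `samples`,
#'   `counts`, `guilds` (named character vector over all OTUs), `richness`
#'   and `library_size`.
#' @export
fungal_dataset <- function(samples, counts, guilds = NULL) {
  samples <- validate_sample_table(as.data.frame(samples))
  counts <- validate_otu_counts(counts)
  miss_meta <- setdiff(rownames(counts), samples$sample_id)
  miss_counts <- setdiff(samples$sample_id, rownames(counts))
  if (length(miss_meta) || length(miss_counts))
    stop("sample-id mismatch between tables: ",
         paste(c(miss_meta, miss_counts), collapse = ", "))
  counts <- counts[samples$sample_id, , drop = FALSE]

  guild_vec <- stats::setNames(rep("unassigned", ncol(counts)), colnames(counts))
  if (!is.null(guilds)) {
    guilds <- as.data.frame(guilds)
    if (!all(c("otu_id", "trophic_group") %in% names(guilds)))
      stop("guild table is missing required column(s): ",
           paste(setdiff(c("otu_id", "trophic_group"), names(guilds)),
                 collapse = ", "))
    if (anyDuplicated(guilds$otu_id)) stop("duplicate otu_id in guild table")
    unknown <- setdiff(guilds$trophic_group, trophic_groups())
    if (length(unknown))
      stop("unrecognised trophic group(s): ", paste(unknown, collapse = ", "))
    extra <- setdiff(guilds$otu_id, colnames(counts))
    if (length(extra))
      stop("guild table lists OTUs absent from the count table: ",
           paste(utils::head(extra, 5), collapse = ", "))
    guild_vec[guilds$otu_id] <- as.character(guilds$trophic_group)
  }

  out <- list(samples = samples, counts = counts, guilds = guild_vec,
              richness = compute_richness(counts),
              library_size = library_sizes(counts))
  class(out) <- "fungal_dataset"
  out
}

#' @export
print.fungal_dataset <- function(x, ...) {
  cat(sprintf(
    "fungal_dataset: %d samples, %d OTUs, %d sites in %d regions\n",
    nrow(x$samples), ncol(x$counts),
    length(unique(x$samples$site)), length(unique(x$samples$region))))
  cat(sprintf("  guild coverage: %.1f%% assigned\n",
              100 * mean(x$guilds != "unassigned")))
  cat(sprintf("  library sizes: %d - %d (median %d)\n",
              min(x$library_size), max(x$library_size),
              as.integer(stats::median(x$library_size))))
  invisible(x)
}

#' Read the three input tables into an aligned dataset
#'
#' Tab-delimited, UTF-8, '.' decimal separator. The OTU table's first column
#' must be `sample_id`; remaining columns are OTU ids with integer cells.
#'
#' @param samples_path path to samples.tsv.
#' @param otus_path path to otus.tsv.
#' @param guilds_path optional path to guilds.tsv (`otu_id`, `trophic_group`);
#'   when omitted every OTU is labelled "unassigned".
#' @param quiet suppress the validation report.
#' @return a [fungal_dataset()].
#' @export
read_dataset <- function(samples_path, otus_path, guilds_path = NULL,
                         quiet = FALSE) {
  for (pp in c(samples_path, otus_path, guilds_path))
    if (!file.exists(pp)) stop("file not found: ", pp)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  otus <- utils::read.delim(otus_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (names(otus)[1] != "sample_id")
    stop("OTU table is missing required column: sample_id (must be first)")
  counts <- as.matrix(otus[, -1, drop = FALSE])
  rownames(counts) <- otus$sample_id
  guilds <- if (!is.null(guilds_path))
    utils::read.delim(guilds_path, stringsAsFactors = FALSE) else NULL
  ds <- fungal_dataset(samples, counts, guilds)
  if (!quiet)
    message(sprintf(
      "read_dataset: %d samples, %d OTUs, %d/%d OTUs guild-assigned",
      nrow(ds$samples), ncol(ds$counts),
      sum(ds$guilds != "unassigned"), ncol(ds$counts)))
  ds
}

#' Write a dataset back to the canonical three-table TSV layout
#'
#' @param dataset a `fungal_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "samples.tsv")
  op <- file.path(dir, "otus.tsv")
  gp <- file.path(dir, "guilds.tsv")
  utils::write.table(dataset$samples[, SAMPLE_COLUMNS], sp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  odf <- data.frame(sample_id = rownames(dataset$counts),
                    dataset$counts, check.names = FALSE)
  utils::write.table(odf, op, sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(otu_id = names(dataset$guilds),
                    trophic_group = unname(dataset$guilds))
  utils::write.table(gdf, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(samples = sp, otus = op, guilds = gp))
}

#' Rarefy an OTU count matrix to a common depth
#'
#' Each retained sample's reads are subsampled uniformly without replacement
#' to exactly `depth`. Samples with fewer than `depth` reads are dropped with
#' a warning (they cannot be rarefied without resampling). A single seeded
#' draw is taken; the same seed reproduces the same table.
#'
#' @param counts samples x OTUs integer matrix (or a `fungal_dataset`).
#' @param depth target library size (>= 1).
#' @param seed integer RNG seed.
#' @return rarefied integer matrix whose row sums all equal `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  if (inherits(counts, "fungal_dataset")) counts <- counts$counts
  if (depth < 1) stop("'depth' must be >= 1")
  lib <- rowSums(counts)
  keep <- lib >= depth
  if (!any(keep))
    stop("rarefaction depth ", depth, " exceeds every library size")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(counts)[!keep], 5), collapse = ", "))
  counts <- counts[keep, , drop = FALSE]
  set.seed(seed)
  out <- counts
  for (j in seq_len(nrow(counts))) {
    row <- counts[j, ]
    if (sum(row) == depth) next
    reads <- rep.int(seq_along(row), row)
    picked <- sample(reads, depth, replace = FALSE)
    out[j, ] <- tabulate(picked, nbins = length(row))
  }
  storage.mode(out) <- "integer"
  out
}
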