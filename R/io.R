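## Readers, writers and community-matrix construction ----------------------
##
## All tables are comma-separated UTF-8 with a header row. Station ids are
## the integer elevation in metres; plots are letters. Trees travel as
## newick. Validation never silently drops data: every excluded or
## suspicious record is reported with file and line number.

stem_schema <- c("station", "plot", "species", "dbh")
ground_schema <- c("station", "plot", "species", "cover_class")
plot_schema <- c("station", "plot", "elevation", "slope", "lai",
                 "canopy_openness", "canopy_height", "tallest_height",
                 "tallest_dbh")
density_schema <- c("level", "name", "density_g_cm3")

#' Write a dataset bundle to delimited files
#'
#' Writes `stems.csv`, `groundcover.csv`, `plots.csv`, `tree.nwk`,
#' `wood_density.csv` and (for synthetic datasets) a `truth.json` sidecar
#' of generating parameters to `dir`.
#'
#' @param dataset a `synthetic_dataset` or a bundle from
#'   [read_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(dataset$stems, file.path(dir, "stems.csv"),
            row.names = FALSE)
  write.csv(dataset$ground_cover, file.path(dir, "groundcover.csv"),
            row.names = FALSE)
  write.csv(dataset$environment, file.path(dir, "plots.csv"),
            row.names = FALSE)
  ape::write.tree(dataset$phylogeny, file.path(dir, "tree.nwk"))
  wd <- dataset$wood_density
  wdf <- rbind(
    data.frame(level = "species", name = names(wd$species_level),
               density_g_cm3 = unname(wd$species_level)),
    data.frame(level = "genus", name = names(wd$genus_level),
               density_g_cm3 = unname(wd$genus_level)),
    data.frame(level = "default", name = "site",
               density_g_cm3 = wd$site_default))
  write.csv(wdf, file.path(dir, "wood_density.csv"), row.names = FALSE)
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    truth$optima <- as.list(truth$optima)
    truth$tolerances <- as.list(truth$tolerances)
    truth$ground_optima <- as.list(truth$ground_optima)
    truth$ground_tolerances <- as.list(truth$ground_tolerances)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

check_schema <- function(df, schema, file) {
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop_elevgrad(sprintf("%s: missing column(s) %s", file,
                          paste(missing, collapse = ", ")),
                  "malformed_file")
}

#' Read and validate a dataset bundle from delimited files
#'
#' Reads the stem, ground-cover, plot-environment, phylogeny and
#' wood-density files, enforces the type invariants (dbh at or above the
#' census minimum, cover classes in 0..6, one environment record per
#' plot, all plots referenced by records present) and reports species
#' present in the data but absent from the tree as a validation warning.
#'
#' @param stems,ground_cover,plots,tree,wood_density file paths.
#' @param min_dbh census minimum dbh (cm).
#' @return a validated bundle (list with class `gradient_bundle`):
#'   `stems`, `ground_cover`, `environment`, `phylogeny`, `wood_density`,
#'   `validation` (character vector of warnings raised).
#' @export
read_dataset <- function(stems, ground_cover, plots, tree, wood_density,
                         min_dbh = 2) {
  for (f in c(stems, ground_cover, plots, tree, wood_density))
    if (!file.exists(f))
      stop_elevgrad(paste0("file not found: ", f), "malformed_file")
  stems_df <- read.csv(stems, stringsAsFactors = FALSE)
  ground_df <- read.csv(ground_cover, stringsAsFactors = FALSE)
  plots_df <- read.csv(plots, stringsAsFactors = FALSE)
  phy <- ape::read.tree(tree)
  wd_df <- read.csv(wood_density, stringsAsFactors = FALSE)
  check_schema(stems_df, stem_schema, stems)
  check_schema(ground_df, ground_schema, ground_cover)
  check_schema(plots_df, plot_schema, plots)
  check_schema(wd_df, density_schema, wood_density)

  bad <- which(!is.finite(stems_df$dbh) | stems_df$dbh < min_dbh)
  if (length(bad))
    stop_elevgrad(sprintf(
      "%s: line %d: dbh = %s below census minimum %g cm",
      stems, bad[1] + 1L, format(stems_df$dbh[bad[1]]), min_dbh),
      "validation_error")
  if (any(stems_df$station == "" | stems_df$plot == ""))
    stop_elevgrad(paste0(stems, ": empty station/plot id"),
                  "validation_error")
  bad <- which(!(ground_df$cover_class %in% 0:6))
  if (length(bad))
    stop_elevgrad(sprintf("%s: line %d: cover_class = %s outside 0..6",
                          ground_cover, bad[1] + 1L,
                          format(ground_df$cover_class[bad[1]])),
                  "validation_error")
  key <- paste0(plots_df$station, plots_df$plot)
  if (anyDuplicated(key))
    stop_elevgrad(paste0(plots, ": duplicate plot record(s): ",
                         paste(key[duplicated(key)], collapse = ", ")),
                  "validation_error")
  refs <- unique(c(paste0(stems_df$station, stems_df$plot),
                   paste0(ground_df$station, ground_df$plot)))
  orphan <- setdiff(refs, key)
  if (length(orphan))
    stop_elevgrad(paste0("records reference unknown plot(s): ",
                         paste(orphan, collapse = ", ")),
                  "validation_error")

  validation <- character(0)
  missing_sp <- setdiff(unique(stems_df$species), phy$tip.label)
  if (length(missing_sp)) {
    msg <- paste0("species absent from the phylogeny: ",
                  paste(missing_sp, collapse = ", "))
    validation <- c(validation, msg)
    warning(msg)
  }
  def <- wd_df$level == "default"
  site_default <- if (any(def)) wd_df$density_g_cm3[which(def)[1]] else 0.56
  wdt <- wood_density_table(wd_df[!def, , drop = FALSE],
                            site_default = site_default)
  structure(list(stems = stems_df, ground_cover = ground_df,
                 environment = plots_df, phylogeny = phy,
                 wood_density = wdt, validation = validation),
            class = "gradient_bundle")
}

#' Assign stems to strata by dbh
#'
#' Half-open intervals: understorey `[b1, b2)`, subcanopy `[b2, b3)`,
#' canopy `[b3, Inf)`.
#'
#' @param dbh numeric vector (cm).
#' @param bounds the three thresholds (cm).
#' @return factor with levels `understorey`, `subcanopy`, `canopy`.
#' @export
assign_stratum <- function(dbh, bounds = c(2, 10, 30)) {
  cut(dbh, breaks = c(bounds, Inf), right = FALSE,
      labels = c("understorey", "subcanopy", "canopy"))
}

#' Build a community matrix from a dataset bundle
#'
#' Aggregates stem (or ground-cover) records into a sites x species
#' matrix at plot or station level. Station-level presence is the union
#' over the station's plots. Ground-cover matrices use the ordinal cover
#' class converted to a pseudo-abundance (abundance form) or presence.
#'
#' @param bundle a `gradient_bundle` or `synthetic_dataset`.
#' @param level `"plot"` or `"station"`.
#' @param form `"abundance"` or `"presence"`.
#' @param strata character subset of `c("understorey", "subcanopy",
#'   "canopy")`, or `"ground"` for ground-cover records.
#' @param dbh_bounds stratum thresholds (cm).
#' @return sites x species matrix with a `stratum` attribute.
#' @export
build_community_matrices <- function(bundle, level = c("plot", "station"),
                                     form = c("abundance", "presence"),
                                     strata = c("understorey",
                                                "subcanopy", "canopy"),
                                     dbh_bounds = c(2, 10, 30)) {
  level <- match.arg(level)
  form <- match.arg(form)
  if (!length(strata))
    stop_elevgrad("empty strata selection", "invalid_argument")
  if (identical(strata, "ground")) {
    rec <- bundle$ground_cover
    if (!nrow(rec))
      stop_elevgrad("no ground-cover records", "invalid_argument")
    value <- cover_class_to_pseudoabundance(rec$cover_class)
  } else {
    if (!all(strata %in% c("understorey", "subcanopy", "canopy")))
      stop_elevgrad("unknown strata selection", "invalid_argument")
    rec <- bundle$stems
    keep <- assign_stratum(rec$dbh, dbh_bounds) %in% strata
    rec <- rec[keep, , drop = FALSE]
    if (!nrow(rec))
      stop_elevgrad("no stems in the selected strata",
                    "invalid_argument")
    value <- rep(1L, nrow(rec))
  }
  site <- if (level == "plot") paste0(rec$station, rec$plot) else
    as.character(rec$station)
  tab <- tapply(value, list(site, rec$species), sum, default = 0)
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  ## plots with no records in the stratum are genuine zero communities
  env <- bundle$environment
  if (!is.null(env)) {
    all_sites <- if (level == "plot")
      unique(paste0(env$station, env$plot)) else
        unique(as.character(env$station))
    missing <- setdiff(all_sites, rownames(m))
    if (length(missing)) {
      zeros <- matrix(0, nrow = length(missing), ncol = ncol(m),
                      dimnames = list(missing, colnames(m)))
      m <- rbind(m, zeros)
    }
  }
  ## order rows by station then plot
  m <- m[order(rownames(m)), , drop = FALSE]
  if (form == "presence") m[] <- as.numeric(m > 0)
  attr(m, "stratum") <- paste(strata, collapse = "+")
  attr(m, "level") <- level
  attr(m, "form") <- form
  m
}
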