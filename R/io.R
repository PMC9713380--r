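#' Read a discovery/replication summary-statistic table
#'
#' Reads a tab-delimited file with a header row and a declarative column
#' mapping. Each study side supplies either a z-score column or a
#' beta/standard-error pair (converted as `z = beta / se`); p-values are
#' never accepted in place of z-scores because they lose the direction of
#' effect. Missing values may be written `.` or left empty and are
#' rejected (every variant needs both statistics). Duplicate variant
#' identifiers are rejected rather than silently deduplicated.
#'
#' @param path Path to a TSV file.
#' @param column_map Named list mapping the roles to column names in the
#'   file. Required role: `variant_id`. For the discovery side either
#'   `z_discovery` or both `beta_discovery` and `se_discovery`; likewise
#'   `z_replication` or `beta_replication`/`se_replication`.
#' @param design Optional [study_design()]; when given, significance flags
#'   are computed at load time (otherwise they are computed at fit time).
#' @return A list with `table` (the parsed `data.frame`, row order
#'   preserved) and `data` (a [paired_zscores()]).
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_pair_small.tsv", package = "gwrep")
#' read_summary_stats(f)$data[1:3, ]
read_summary_stats <- function(path,
                               column_map = list(
                                 variant_id = "variant_id",
                                 z_discovery = "z_discovery",
                                 z_replication = "z_replication"),
                               design = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = c(".", "", "NA"))
  get_col <- function(role) {
    nm <- column_map[[role]]
    if (is.null(nm)) return(NULL)
    if (!nm %in% names(tab))
      stop("declared column '", nm, "' (role ", role, ") not found in ", path)
    tab[[nm]]
  }
  parse_num <- function(x, role) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out))
    if (length(bad))
      stop("non-numeric or missing value in column for role '", role,
           "' at row ", bad[1])
    out
  }
  ids <- get_col("variant_id")
  if (is.null(ids)) stop("column_map must declare a 'variant_id' column")
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate variant_id '", ids[dup[1]], "' at row ", dup[1])

  side_z <- function(z_role, beta_role, se_role) {
    z_raw <- get_col(z_role)
    beta_raw <- get_col(beta_role)
    se_raw <- get_col(se_role)
    if (!is.null(z_raw) && (!is.null(beta_raw) || !is.null(se_raw)))
      stop("declare either ", z_role, " or ", beta_role, "/", se_role,
           ", not both")
    if (!is.null(z_raw)) return(parse_num(z_raw, z_role))
    if (is.null(beta_raw) || is.null(se_raw))
      stop("declare either ", z_role, " or both ", beta_role, " and ", se_role)
    beta <- parse_num(beta_raw, beta_role)
    se <- parse_num(se_raw, se_role)
    bad <- which(se <= 0)
    if (length(bad))
      stop("non-positive standard error (role ", se_role, ") at row ", bad[1])
    beta / se
  }
  z1 <- side_z("z_discovery", "beta_discovery", "se_discovery")
  z2 <- side_z("z_replication", "beta_replication", "se_replication")
  data <- paired_zscores(z1, z2, variant_ids = ids, design = design)
  list(table = tab, data = data)
}

#' Write paired z-scores as a summary-statistic TSV
#'
#' Writes the canonical three-column table (`variant_id`, `z_discovery`,
#' `z_replication`) consumed by [read_summary_stats()]; the round trip
#' preserves values to full double precision.
#'
#' @param data A [paired_zscores()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(data, path) {
  stopifnot(inherits(data, "paired_zscores"))
  out <- data.frame(variant_id = data$variant_id,
                    z_discovery = sprintf("%.17g", data$z_discovery),
                    z_replication = sprintf("%.17g", data$z_replication))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
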