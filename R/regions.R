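# Experimental forebrain region grid (6 coronal sections A-F, each cut into
# a 3x3 grid of cells 1-9) and the matching-accuracy score between
# predicted and observed damaged regions.

REGION_SECTIONS <- LETTERS[1:6]
# Bregma cut locations (mm) bounding sections A..F
BREGMA_CUTS <- c(4, 2, 0, -2, -4, -6, -9)

# Region statuses that are named in the running text (transcription
# confidence "text"); all other labels in the packaged fixture are
# constructed stand-ins tagged confidence "figure".
TEXT_DAMAGED <- c("A4", "A6", "C1", "C3", "E8", "F4", "F6")
TEXT_INTACT <- c("B1", "B2", "B3", "C2", "D2", "D7", "D9", "D1", "D3")

#' Region identifier
#'
#' @param section section letter `A`-`F` (rostral to caudal).
#' @param cell cell number 1-9 within the section's 3x3 grid.
#' @return character id like `"E8"`.
#' @export
region_id <- function(section, cell) {
  if (!all(section %in% REGION_SECTIONS))
    stop("section must be one of A-F", call. = FALSE)
  cell <- as.integer(cell)
  if (any(is.na(cell)) || any(cell < 1L) || any(cell > 9L))
    stop("cell must be 1-9", call. = FALSE)
  paste0(section, cell)
}

#' Load the experimental region labels
#'
#' Reads the packaged region-label fixture: the 6 x 9 forebrain grid with
#' per-region status (`damaged` / `intact` / `unlabeled`), evidence tag and
#' transcription confidence. Exactly 53 regions carry assay labels, 8 of
#' them damaged (elevated oxidative stress); the text-named regions are
#' tagged `confidence = "text"`, the rest are constructed stand-ins tagged
#' `"figure"` (the source figure is not distributed with the package).
#' Invariants are enforced on load; a malformed file fails with the
#' offending row.
#'
#' @param path fixture CSV; defaults to the packaged file.
#' @return object of class `region_labels`: data frame with columns
#'   `section`, `cell`, `region`, `status`, `evidence`, `confidence`.
#' @examples
#' labs <- load_experimental_labels()
#' sum(labs$status == "damaged")  # 8
#' @export
load_experimental_labels <- function(path = system.file(
  "extdata", "region_labels_synthetic.csv", package = "btbimech")) {
  if (!nzchar(path) || !file.exists(path))
    stop("region label fixture not found", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section", "cell", "status", "evidence", "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed fixture, missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(df))) {
    if (!df$section[i] %in% REGION_SECTIONS ||
        is.na(df$cell[i]) || df$cell[i] < 1 || df$cell[i] > 9 ||
        !df$status[i] %in% c("damaged", "intact", "unlabeled") ||
        !df$confidence[i] %in% c("text", "figure"))
      stop(sprintf("malformed fixture row %d (%s%s)", i,
                   df$section[i], df$cell[i]), call. = FALSE)
  }
  df$region <- region_id(df$section, df$cell)
  if (nrow(df) != 54L || anyDuplicated(df$region))
    stop("fixture must cover the 54 grid cells exactly once", call. = FALSE)
  if (sum(df$status != "unlabeled") != 53L)
    stop("fixture must carry labels for exactly 53 regions", call. = FALSE)
  if (sum(df$status == "damaged") != 8L)
    stop("fixture must mark exactly 8 damaged regions", call. = FALSE)
  if (!all(df$status[df$region %in% TEXT_DAMAGED] == "damaged"))
    stop("text-named damaged regions mislabelled", call. = FALSE)
  if (!all(df$status[df$region %in% TEXT_INTACT] == "intact"))
    stop("text-named intact regions mislabelled", call. = FALSE)
  structure(df[order(df$section, df$cell), ],
            class = c("region_labels", "data.frame"))
}

#' Matching accuracy between predicted and observed region damage
#'
#' \deqn{100 \cdot \frac{\#\{predicted\ damaged = observed\ damaged\} +
#'   \#\{predicted\ intact = observed\ intact\}}{\#\ jointly\ covered\
#'   labelled\ regions}}
#'
#' Unlabelled regions and regions missing from either map are excluded from
#' the denominator.
#'
#' @param pred prediction map: data frame with columns `section`, `cell`
#'   (or `region`) and logical `predicted` (damaged yes/no).
#' @param obs a [load_experimental_labels()] result (or any data frame with
#'   `region` and `status`).
#' @param tissue optional tissue filter; applied only if `obs` carries a
#'   `tissue` column (the grid-to-tissue assignment is not part of the
#'   packaged labels).
#' @return accuracy in percent.
#' @examples
#' obs <- load_experimental_labels()
#' pred <- data.frame(region = obs$region,
#'                    predicted = obs$status == "damaged")
#' matching_accuracy(pred, obs)  # 100
#' @export
matching_accuracy <- function(pred, obs, tissue = NULL) {
  pred <- as.data.frame(pred)
  obs <- as.data.frame(obs)
  if (!"region" %in% names(pred)) {
    if (!all(c("section", "cell") %in% names(pred)))
      stop("'pred' needs a 'region' or 'section'+'cell' columns",
           call. = FALSE)
    pred$region <- region_id(pred$section, pred$cell)
  }
  if (!"predicted" %in% names(pred))
    stop("'pred' needs a logical 'predicted' column", call. = FALSE)
  if (!is.null(tissue) && "tissue" %in% names(obs))
    obs <- obs[obs$tissue == tissue, ]
  obs <- obs[obs$status %in% c("damaged", "intact"), ]
  m <- merge(pred[, c("region", "predicted")],
             obs[, c("region", "status")], by = "region")
  if (nrow(m) == 0L)
    stop("no jointly covered labelled regions", call. = FALSE)
  100 * mean(m$predicted == (m$status == "damaged"))
}

#' Aggregate material-point exceedances into a region prediction map
#'
#' A region is predicted damaged if at least one of its points exceeds the
#' criterion threshold (`rule = "any"`, the default conservative rule), or
#' if at least `fraction` of its points do (`rule = "fraction"`).
#'
#' @param points data frame with columns `region` (or `section` + `cell`)
#'   and either logical `exceeded` or numeric `peak` (compared against
#'   `criterion$threshold`).
#' @param criterion a [criterion_spec()]; needed when `points` carries
#'   `peak` rather than `exceeded`, and recorded in the output.
#' @param rule `"any"` or `"fraction"`.
#' @param fraction exceedance fraction for `rule = "fraction"` (default
#'   0.5).
#' @return prediction map: data frame with `region`, `predicted`,
#'   `criterion`.
#' @export
aggregate_points_to_regions <- function(points, criterion = NULL,
                                        rule = c("any", "fraction"),
                                        fraction = 0.5) {
  rule <- match.arg(rule)
  points <- as.data.frame(points)
  if (!"region" %in% names(points)) {
    if (!all(c("section", "cell") %in% names(points)))
      stop("points need a 'region' or 'section'+'cell' columns",
           call. = FALSE)
    points$region <- region_id(points$section, points$cell)
  }
  if (!grepl("^[A-F][1-9]$", points$region[1]) ||
      !all(grepl("^[A-F][1-9]$", points$region)))
    stop("point with unknown region id: ",
         points$region[!grepl("^[A-F][1-9]$", points$region)][1],
         call. = FALSE)
  if (!"exceeded" %in% names(points)) {
    if (is.null(criterion) || !"peak" %in% names(points))
      stop("points need an 'exceeded' flag or 'peak' plus a criterion",
           call. = FALSE)
    points$exceeded <- points$peak >= criterion$threshold
  }
  agg <- stats::aggregate(exceeded ~ region, data = points,
                          FUN = function(x)
                            if (rule == "any") any(x) else mean(x) >= fraction)
  data.frame(region = agg$region, predicted = as.logical(agg$exceeded),
             criterion = if (is.null(criterion)) NA_character_
                         else criterion$name)
}

#' Read / write region prediction maps as CSV
#'
#' Columns: `section`, `cell`, `predicted`, `criterion`.
#'
#' @param path CSV path.
#' @return prediction map data frame.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section", "cell", "predicted")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed predictions CSV, missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$region <- region_id(df$section, df$cell)
  df$predicted <- as.logical(df$predicted)
  df
}

#' @rdname read_predictions
#' @param pred prediction map with `region` (or `section`+`cell`),
#'   `predicted` and optionally `criterion`.
#' @export
write_predictions <- function(pred, path) {
  pred <- as.data.frame(pred)
  if (!all(c("section", "cell") %in% names(pred)) &&
      "region" %in% names(pred)) {
    pred$section <- substr(pred$region, 1, 1)
    pred$cell <- as.integer(substr(pred$region, 2, 2))
  }
  if (!"criterion" %in% names(pred)) pred$criterion <- NA_character_
  utils::write.csv(pred[, c("section", "cell", "predicted", "criterion")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Confusion table of a prediction against the labels
#'
#' @inheritParams matching_accuracy
#' @return 2x2 table of predicted vs observed damaged/intact over jointly
#'   covered labelled regions.
#' @export
region_confusion <- function(pred, obs, tissue = NULL) {
  pred <- as.data.frame(pred)
  if (!"region" %in% names(pred))
    pred$region <- region_id(pred$section, pred$cell)
  obs <- as.data.frame(obs)
  obs <- obs[obs$status %in% c("damaged", "intact"), ]
  m <- merge(pred[, c("region", "predicted")],
             obs[, c("region", "status")], by = "region")
  table(predicted = ifelse(m$predicted, "damaged", "intact"),
        observed = m$status)
}
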