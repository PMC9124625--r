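# Versioned on-disk course fixture: one JSON metadata document plus raw
# little-endian float64 containers for dose grids ("cordshift-fixture-v1").

FIXTURE_SCHEMA <- "cordshift-fixture-v1"

.structure_to_list <- function(s) list(
  name = s$name, role = s$role,
  contours = lapply(s$contours, function(ct)
    list(y = ct$y_slice, points = unname(ct$points))))

.structure_from_list <- function(l) {
  contours <- lapply(l$contours, function(ct)
    contour(ct$y, matrix(unlist(ct$points), ncol = 2, byrow = !is.matrix(ct$points)),
            check = FALSE))
  rt_structure(l$name, contours, role = l$role)
}

.write_grid_bin <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
}

.read_grid_bin <- function(path, dim, origin, spacing) {
  n <- prod(dim)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(v) != n)
    stop(sprintf("grid file '%s' is truncated", basename(path)))
  dose_grid(array(v, dim), origin, spacing)
}

#' Write a course fixture directory
#'
#' Serializes a sampled (or clinical) course to `dir`: `course.json` holds the
#' schema version, region partition, structures, planned doses and the long
#' records table; dose grids go to `grids/*.f64` as raw little-endian doubles
#' (byte-stable round trip).
#'
#' @param course a [sample_course()] result, or any list with compatible
#'   `records`, `planned`, `phantom` fields.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(course, dir) {
  dir.create(file.path(dir, "grids"), recursive = TRUE, showWarnings = FALSE)
  ph <- course$phantom
  grids <- list()
  if (!is.null(ph$plan)) {
    .write_grid_bin(ph$plan, file.path(dir, "grids", "plan.f64"))
    grids$plan <- list(file = "grids/plan.f64", dim = dim(ph$plan$values),
                       origin = ph$plan$origin, spacing = ph$plan$spacing)
  }
  meta <- list(
    schema = FIXTURE_SCHEMA,
    partition = lapply(unclass(ph$partition), identity),
    planned = as.list(course$planned),
    n_fractions = ph$spec$n_fractions,
    structures = list(.structure_to_list(ph$external),
                      .structure_to_list(ph$sc)),
    records = as.list(course$records),
    grids = grids)
  jsonlite::write_json(meta, file.path(dir, "course.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.fixture_fail <- function(field, why)
  stop(sprintf("fixture validation failed at '%s': %s", field, why),
       call. = FALSE)

#' Read a course fixture directory
#'
#' Validates the schema version and required fields, then reconstructs the
#' course object graph (records, planned doses, partition, structures and any
#' dose grids).
#'
#' @param dir fixture directory written by [write_fixture()].
#' @return list with `records`, `planned`, `partition`, `structures` (named),
#'   `plan` (course-scale [dose_grid()] or `NULL`), `n_fractions`.
#' @export
read_fixture <- function(dir) {
  path <- file.path(dir, "course.json")
  if (!file.exists(path)) .fixture_fail("course.json", "file not found")
  meta <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = TRUE)
  if (is.null(meta$schema)) .fixture_fail("schema", "missing")
  if (!identical(meta$schema, FIXTURE_SCHEMA))
    .fixture_fail("schema", sprintf("version '%s' is not supported (expected %s)",
                                    meta$schema, FIXTURE_SCHEMA))
  for (key in c("partition", "records", "planned"))
    if (is.null(meta[[key]])) .fixture_fail(key, "missing required key")
  records <- as.data.frame(meta$records, stringsAsFactors = FALSE)
  for (col in c("dx", "dy", "dz"))
    if (!is.null(records[[col]]) && any(!is.finite(records[[col]])))
      .fixture_fail(paste0("records.", col), "non-finite values")
  partition <- region_partition(lapply(meta$partition, as.numeric))
  structures <- list()
  for (sl in meta$structures) {
    s <- .structure_from_list(sl)
    structures[[s$name]] <- s
  }
  plan <- NULL
  if (!is.null(meta$grids$plan)) {
    g <- meta$grids$plan
    plan <- .read_grid_bin(file.path(dir, g$file), as.integer(g$dim),
                           as.numeric(g$origin), as.numeric(g$spacing))
  }
  list(records = records,
       planned = unlist(meta$planned),
       partition = partition, structures = structures, plan = plan,
       n_fractions = meta$n_fractions)
}
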