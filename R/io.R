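# Text-based persistence: record bundles (full-precision CSV + JSON
# metadata), contour CSV, a JSON mesh schema and a legacy-ASCII VTK
# unstructured-grid writer/reader for meshes and displacement fields.

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(M, path, colnames) {
  df <- as.data.frame(apply(M, 2, fmt_num))
  names(df) <- colnames
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_matrix_csv <- function(path) {
  M <- as.matrix(utils::read.csv(path, colClasses = "numeric"))
  dimnames(M) <- NULL
  M
}

#' Write a virtual tonometry record to a directory bundle
#'
#' Persists an `nct_record` as plain text: JSON metadata (geometry
#' parameters, materials, pulse, state scalars, seed) plus full-precision
#' (`%.17g`) CSV files for the stress-free coordinates, prestress and
#' per-state displacement/external-force fields, the loading trace and the
#' contours. Full precision makes the displacement round trip bit-exact,
#' which the machine-precision recovery property relies on.
#'
#' @param record An `nct_record`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_nct_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- record$model
  mat <- model$groups$cornea$material
  meta <- list(
    schema = "egmeye-nct-bundle",
    schema_version = 1L,
    material_tag = record$material_tag,
    material = mat[c("K", "mu", "k1", "k2", "tension_only")],
    aux = unclass(model$aux),
    params = unclass(model$params),
    pulse = record$pulse,
    cavity = list(V0 = model$cavity$V0, p0 = model$cavity$p0,
                  KW = model$cavity$KW),
    seed = record$seed,
    z_apex_invivo = record$z_apex_invivo,
    applanation = record$applanation,
    states = lapply(record$states, function(s)
      s[c("factor", "p_c", "V", "DefA")]))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_matrix_csv(model$nodes, file.path(dir, "nodes.csv"),
                   c("x", "y", "z"))
  write_matrix_csv(record$U_pre, file.path(dir, "U_pre.csv"),
                   c("ux", "uy", "uz"))
  for (s in seq_along(record$states)) {
    write_matrix_csv(record$states[[s]]$U,
                     file.path(dir, sprintf("state%d_U.csv", s)),
                     c("ux", "uy", "uz"))
    write_matrix_csv(matrix(record$states[[s]]$f_ext, ncol = 1),
                     file.path(dir, sprintf("state%d_fext.csv", s)), "f")
    write_contours(record$contours[[s]],
                   file.path(dir, sprintf("contours%d.csv", s)))
  }
  utils::write.csv(record$trace, file.path(dir, "trace.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a virtual tonometry record bundle
#'
#' Rebuilds the model deterministically from the stored geometry
#' parameters, replaces its reference coordinates with the stored
#' stress-free geometry and reloads all fields.
#'
#' @param dir Bundle directory written by [write_nct_record()].
#' @return An `nct_record`.
#' @export
read_nct_record <- function(dir) {
  mf <- file.path(dir, "metadata.json")
  if (!file.exists(mf))
    stop("not a record bundle (metadata.json missing): ", dir, call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$schema, "egmeye-nct-bundle") ||
      !identical(as.integer(meta$schema_version), 1L))
    stop("unsupported bundle schema version: ", meta$schema_version,
         call. = FALSE)
  pl <- meta$params
  params <- eye_geometry_params(
    Rr = pl$Rr, Rz = pl$Rz, cct = pl$cct,
    peripheral_thickness = pl$peripheral_thickness,
    limbus_start = pl$limbus_start, limbus_width = pl$limbus_width,
    n_planform = pl$n_planform, n_layers = pl$n_layers,
    n_limbus = pl$n_limbus, apex_disc = pl$apex_disc,
    cavity_KW = pl$cavity_KW, iop_mmHg = pl$iop_mmHg)
  mat <- material_parameters(K = meta$material$K, mu = meta$material$mu,
                             k1 = meta$material$k1, k2 = meta$material$k2,
                             tension_only = meta$material$tension_only)
  aux <- auxiliary_materials(E_Li = meta$aux$E_Li, E_Sc = meta$aux$E_Sc,
                             E_Le = meta$aux$E_Le, nu = meta$aux$nu)
  model <- build_eye_mesh(params, cornea_material = mat, aux = aux)
  model <- model_set_coords(model, read_matrix_csv(file.path(dir, "nodes.csv")))
  model$cavity$V0 <- meta$cavity$V0
  model$cavity$p0 <- meta$cavity$p0
  model$cavity$KW <- meta$cavity$KW

  n_states <- length(meta$states$factor)
  states <- vector("list", n_states)
  contours <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    uf <- file.path(dir, sprintf("state%d_U.csv", s))
    if (!file.exists(uf))
      stop(sprintf("bundle is missing state %d (%s)", s, basename(uf)),
           call. = FALSE)
    states[[s]] <- list(
      factor = meta$states$factor[s],
      U = read_matrix_csv(uf),
      f_ext = as.numeric(read_matrix_csv(
        file.path(dir, sprintf("state%d_fext.csv", s)))),
      p_c = meta$states$p_c[s], V = meta$states$V[s],
      DefA = meta$states$DefA[s])
    contours[[s]] <- read_contours(file.path(dir,
                                             sprintf("contours%d.csv", s)))
  }
  structure(
    list(model = model, U_pre = read_matrix_csv(file.path(dir, "U_pre.csv")),
         states = states, contours = contours,
         trace = tibble::as_tibble(utils::read.csv(file.path(dir, "trace.csv"))),
         pulse = meta$pulse, material_tag = meta$material_tag,
         seed = meta$seed, applanation = meta$applanation,
         z_apex_invivo = meta$z_apex_invivo),
    class = "nct_record")
}

#' Write / read deformation contours as CSV
#'
#' Columns `surface`, `r_mm`, `z_mm`; metadata (`DefA`, `CCT`, IOP, load
#' factor) in a JSON sidecar of the same base name. Rows are re-sorted by
#' `r` within each surface on reading, so row order in the file is
#' irrelevant.
#'
#' @param contours A `"contour_pair"`.
#' @param path CSV file path.
#' @return `path` ([write_contours()]) or a `"contour_pair"`
#'   ([read_contours()]).
#' @export
write_contours <- function(contours, path) {
  df <- contours$contour
  out <- data.frame(surface = df$surface, r_mm = fmt_num(df$r),
                    z_mm = fmt_num(df$z))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(DefA = contours$DefA, CCT = contours$CCT,
         iop_MPa = contours$iop_MPa, factor = contours$factor),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric",
                                             "numeric"))
  df <- df[order(df$surface, df$r_mm), ]
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  structure(list(
    contour = tibble::tibble(surface = df$surface, r = df$r_mm,
                             z = df$z_mm),
    DefA = meta$DefA, CCT = meta$CCT, iop_MPa = meta$iop_MPa,
    factor = meta$factor), class = "contour_pair")
}

#' Write a mesh (plus optional nodal fields) as legacy ASCII VTK
#'
#' Unstructured grid with hexahedral cells (VTK cell type 12); nodal
#' vector fields are written as POINT_DATA. Readable by ParaView and by
#' [read_vtk_mesh()].
#'
#' @param model An eye model (or any list with `nodes` and `groups` with
#'   `conn`).
#' @param path Output `.vtk` file.
#' @param point_data Named list of N x 3 matrices (e.g. `list(u = U)`).
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(model, path, point_data = list()) {
  nodes <- model$nodes
  conn <- do.call(rbind, lapply(model$groups, `[[`, "conn"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "egmeye unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes))), con)
  writeLines(apply(nodes, 1, function(r) paste(fmt_num(r), collapse = " ")),
             con)
  writeLines(sprintf("CELLS %d %d", nrow(conn), nrow(conn) * 9L), con)
  writeLines(apply(conn, 1, function(r)
    paste(c(8L, r - 1L), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(conn)), con)
  writeLines(rep("12", nrow(conn)), con)
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
    for (nm in names(point_data)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(point_data[[nm]], 1, function(r)
        paste(fmt_num(r), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid written by this package
#'
#' @param path `.vtk` file.
#' @return A list with `nodes` (N x 3), `conn` (E x 8, 1-based) and
#'   `point_data` (named list of N x 3 matrices).
#' @export
read_vtk_mesh <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  nodes <- do.call(rbind, lapply(ln[(ip + 1):(ip + np)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  ic <- grep("^CELLS", ln)[1]
  nc <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  conn <- do.call(rbind, lapply(ln[(ic + 1):(ic + nc)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (v[1] != 8L) stop("only hex8 cells supported", call. = FALSE)
    v[-1] + 1L
  }))
  point_data <- list()
  for (iv in grep("^VECTORS", ln)) {
    nm <- strsplit(ln[iv], " ")[[1]][2]
    point_data[[nm]] <- do.call(rbind,
      lapply(ln[(iv + 1):(iv + np)], function(s)
        as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  }
  list(nodes = nodes, conn = conn, point_data = point_data)
}

#' Write / read the internal JSON mesh schema
#'
#' Nodes, per-group connectivity and material tags, node sets and facet
#' sets of a model, as documented JSON.
#'
#' @param model An eye model.
#' @param path `.json` file path.
#' @return `path` or the parsed list.
#' @export
write_mesh_json <- function(model, path) {
  jsonlite::write_json(list(
    schema = "egmeye-mesh", schema_version = 1L,
    nodes = model$nodes,
    groups = lapply(model$groups, function(g) list(conn = g$conn)),
    node_sets = model$node_sets,
    facet_sets = model$facet_sets,
    fixed_dofs = model$bc$fixed_dofs), path, digits = NA)
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
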