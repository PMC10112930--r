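#' Serialize a tissue mesh to JSON
#'
#' Writes the mesh as a JSON document with top-level arrays `nodes`,
#' `edges`, `cells` and `cable_loop` mirroring the mesh tables, a
#' `schema_version` field, and full-precision positions so that a
#' write/read round trip reproduces every field bit-exactly.
#'
#' @param mesh A `tissue_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_mesh_json()]
#' @export
write_mesh_json <- function(mesh, path) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  doc <- list(
    schema_version = 1L,
    n_coronae = mesh$n_coronae,
    edge_length = mesh$edge_length,
    cable_after_corona = mesh$cable_after_corona,
    core_coronae = mesh$core_coronae,
    centre = mesh$centre,
    nodes = list(id = mesh$nodes$id,
                 position = unname(mesh_positions(mesh)),
                 kind = mesh$nodes$kind,
                 region = mesh$nodes$region),
    edges = list(id = mesh$edges$id,
                 endpoints = unname(cbind(mesh$edges$from, mesh$edges$to)),
                 kind = mesh$edges$kind,
                 rest_length = mesh$edges$rest_length,
                 modulus = mesh$edges$modulus,
                 is_cable = mesh$edges$is_cable,
                 is_active = mesh$edges$is_active),
    cells = list(id = mesh$cells$id,
                 corona_index = mesh$cells$corona,
                 centre_node = mesh$cells$centre_node,
                 region = mesh$cells$region,
                 boundary_nodes = mesh$cells$boundary),
    cable_loop = mesh$cable_loop)
  # digits = I(17) guarantees exact binary round-tripping of doubles
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a tissue mesh from JSON
#'
#' @param path Path to a file written by [write_mesh_json()].
#' @return A `tissue_mesh`.
#' @export
read_mesh_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    stop("unsupported mesh schema version: ", doc$schema_version)
  nodes <- data.frame(id = as.integer(doc$nodes$id),
                      x = as.numeric(doc$nodes$position[, 1L]),
                      y = as.numeric(doc$nodes$position[, 2L]),
                      kind = doc$nodes$kind,
                      region = as.character(doc$nodes$region),
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = as.integer(doc$edges$id),
                      from = as.integer(doc$edges$endpoints[, 1L]),
                      to = as.integer(doc$edges$endpoints[, 2L]),
                      kind = doc$edges$kind,
                      rest_length = as.numeric(doc$edges$rest_length),
                      modulus = as.numeric(doc$edges$modulus),
                      is_cable = doc$edges$is_cable,
                      is_active = doc$edges$is_active,
                      stringsAsFactors = FALSE)
  cells <- data.frame(id = as.integer(doc$cells$id),
                      corona = as.integer(doc$cells$corona_index),
                      centre_node = as.integer(doc$cells$centre_node),
                      region = as.character(doc$cells$region),
                      stringsAsFactors = FALSE)
  bn <- doc$cells$boundary_nodes
  cells$boundary <- if (is.matrix(bn))
    lapply(seq_len(nrow(bn)), function(i) as.integer(bn[i, ]))
  else lapply(bn, as.integer)
  structure(list(nodes = nodes, edges = edges, cells = cells,
                 cable_loop = as.integer(unlist(doc$cable_loop)),
                 centre = as.numeric(doc$centre),
                 n_coronae = as.integer(doc$n_coronae),
                 edge_length = as.numeric(doc$edge_length),
                 cable_after_corona = as.integer(
                   if (is.null(doc$cable_after_corona)) NA
                   else doc$cable_after_corona),
                 core_coronae = as.integer(
                   if (is.null(doc$core_coronae)) NA else doc$core_coronae)),
            class = "tissue_mesh")
}
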