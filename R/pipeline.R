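#' Run a declarative mesh-processing pipeline
#'
#' Executes an ordered list of stages, each a named list with a `cmd`
#' entry naming a package operation plus its parameters.  Stages exchange
#' meshes through files (VTK legacy by default) so that every intermediate
#' result can be inspected, exactly as running the stages by hand would.
#' Available commands mirror the command-line interface: `fixture`,
#' `connect`, `boolean`, `harmonic_connect`, `tag`, `extend`, `thickness`,
#' `thicken`, `meshsize`, `curvature`, `remesh`, `tetrahedralize`,
#' `volconnect`, `refine`, `tethex`, `validate`.
#'
#' @param config A list of stage lists (or a path to a YAML file holding
#'   one under the key `stages`).
#' @param workdir Directory for intermediate artifacts.
#' @param keep_intermediates Keep per-stage output files.
#' @param verbose Log element counts and tag inventory per stage.
#' @return The final stage's mesh object (invisibly `NULL` for an empty
#'   pipeline).
#' @export
run_pipeline <- function(config, workdir = tempdir(), keep_intermediates = FALSE,
                         verbose = TRUE) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$stages)) config <- config$stages
  }
  if (length(config) == 0L) return(invisible(NULL))
  for (k in seq_along(config)) {
    if (is.null(config[[k]]$cmd))
      stop(sprintf("stage %d has no 'cmd'", k), call. = FALSE)
  }
  current <- NULL
  log1 <- function(...) if (verbose) message(sprintf(...))
  for (k in seq_along(config)) {
    stage <- config[[k]]
    cmd <- stage$cmd
    stage$cmd <- NULL
    if (!is.null(stage$input)) current <- read_mesh(stage$input)
    current <- pipeline_stage(cmd, current, stage)
    if (!is.null(current)) {
      if (inherits(current, "tri_surface"))
        log1("[%d] %s -> %d points, %d cells, tags {%s}", k, cmd,
             nrow(current$points), nrow(current$triangles),
             paste(sort(unique(current$cell_tags)), collapse = ","))
      else if (inherits(current, "tet_mesh"))
        log1("[%d] %s -> %d points, %d tets, tags {%s}", k, cmd,
             nrow(current$points), nrow(current$tets),
             paste(sort(unique(current$cell_tags)), collapse = ","))
      else if (inherits(current, "hex_mesh"))
        log1("[%d] %s -> %d points, %d hexes", k, cmd,
             nrow(current$points), nrow(current$hexes))
      out <- stage$output %||%
        (if (keep_intermediates) file.path(workdir, sprintf("stage_%02d.vtk", k)) else NULL)
      if (!is.null(out)) write_mesh(current, out, format = "vtk")
    }
  }
  invisible(current)
}

pipeline_stage <- function(cmd, current, p) {
  need <- function() {
    if (is.null(current)) stop(sprintf("stage '%s' needs an input mesh", cmd), call. = FALSE)
    current
  }
  p$input <- NULL; p$output <- NULL
  switch(cmd,
    fixture = do.call(make_fixture, p),
    connect = {
      s1 <- read_mesh(p$s1); s2 <- read_mesh(p$s2)
      surface_connection(s1, s2, band_tag = p$band_tag %||% 1L)
    },
    boolean = {
      s1 <- if (!is.null(p$s1)) read_mesh(p$s1) else need()
      s2 <- read_mesh(p$s2)
      boolean_connection(s1, s2, operation = p$op %||% "difference",
                         epsilon = p$eps, h = p$h,
                         clip_both = p$clip_both %||% TRUE,
                         buffer_only = p$buffer_only %||% TRUE)
    },
    harmonic_connect = {
      s_in <- if (!is.null(p$s_in)) read_mesh(p$s_in) else need()
      s_ref <- read_mesh(p$s_ref)
      harmonic_connection(s_in, s_ref,
                          registration = p$registration %||% "none",
                          excluded_tags = p$exclude_tags %||% integer(0),
                          h = p$h)
    },
    tag = {
      s <- need()
      alg <- p$alg %||% "simple"
      switch(alg,
        simple = tag_simple(s, p$field, p$sigma, p$new_tag,
                            invert = p$invert %||% FALSE,
                            excluded_tags = p$exclude %||% integer(0)),
        clip = tag_clip(s, p$field, p$sigma, p$new_tag,
                        invert = p$invert %||% FALSE,
                        excluded_tags = p$exclude %||% integer(0)),
        harmonic = tag_harmonic(s, p$field, p$sigma, p$new_tag,
                                rho = p$rho, invert = p$invert %||% FALSE,
                                excluded_tags = p$exclude %||% integer(0)),
        connectivity = tag_connectivity(s, base_tags = p$base_tags),
        cells = tag_cells(s, p$new_tag, cell_ids = p$cell_ids,
                          seed = p$seed, radius = p$radius),
        stop(sprintf("unknown tag algorithm '%s'", alg), call. = FALSE))
    },
    extend = harmonic_extension(need(), p$field, p$source_tags,
                                zero_tags = p$zero_tags %||% integer(0),
                                normalize = p$normalize %||% FALSE),
    thickness = surface_thickness(need(), p$inner1, p$outer,
                                  internal_tags_2 = p$inner2 %||% integer(0)),
    thicken = surface_thicken(need(), p$sigma, alpha = p$alpha %||% 1,
                              excluded_tags = p$exclude %||% integer(0),
                              invert = p$invert %||% FALSE),
    curvature = mean_curvature(need()),
    meshsize = mesh_size(need(), p$specs, target_tags = p$tags,
                         smooth_iterations = p$smooth %||% 10L),
    remesh = isotropic_remesh(need(), h = p$h, size_field = p$size_field,
                              target_tags = p$tags,
                              iterations = p$iters %||% 10L,
                              preserve_boundary = p$preserve_boundary %||% FALSE),
    tetrahedralize = tetrahedralize(need(), volume_tag = p$volume_tag %||% 1L),
    volconnect = {
      m1 <- read_mesh(p$m1); m2 <- read_mesh(p$m2)
      mesh_connection(m1, m2, tags1 = p$tags1, tags2 = p$tags2, h = p$h)
    },
    refine = refine_mesh(need(), p$field, alpha = p$alpha %||% 1,
                         beta = p$beta %||% 1, m = p$m),
    tethex = tet_to_hex(need(), n_rbs = p$rbs %||% 0L),
    validate = {
      m <- need()
      if (inherits(m, "tri_surface")) validate_surface(m) else validate_tet_mesh(m)
      m
    },
    stop(sprintf("unknown pipeline command '%s'", cmd), call. = FALSE))
}
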