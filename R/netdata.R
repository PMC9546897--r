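#' Load one of the classic netdata networks
#'
#' The four real networks used in the analyses — Les Misérables character
#' co-appearances, the Doubtful Sound dolphin association network, Division
#' I American college football games (fall 2000), and co-purchased US
#' politics books — are distributed by M. Newman at
#' <http://www-personal.umich.edu/~mejn/netdata/> and are not redistributed
#' with this package.  This loader looks for `<name>.gml` in `dir`, then in
#' `getOption("orcflow.netdata_dir")`, then in the package's
#' `extdata/netdata` directory, and finally attempts to download and unzip
#' the file into a per-session cache.
#'
#' @param name One of `"lesmis"`, `"dolphins"`, `"football"`, `"polbooks"`.
#' @param dir Optional directory containing the GML files.
#' @return An igraph object.
#' @export
load_netdata <- function(name = c("lesmis", "dolphins", "football", "polbooks"),
                         dir = NULL) {
  name <- match.arg(name)
  fname <- paste0(name, ".gml")
  candidates <- c(
    if (!is.null(dir)) file.path(dir, fname),
    if (!is.null(getOption("orcflow.netdata_dir")))
      file.path(getOption("orcflow.netdata_dir"), fname),
    system.file("extdata", "netdata", fname, package = "orcflow"),
    file.path(netdata_cache_dir(), fname)
  )
  candidates <- candidates[nzchar(candidates)]
  hit <- candidates[file.exists(candidates)]
  if (length(hit) == 0) {
    fetched <- try(fetch_netdata(name), silent = TRUE)
    if (inherits(fetched, "try-error") || !file.exists(fetched)) {
      stop("netdata file '", fname, "' not found locally and could not be ",
           "downloaded; place it in a directory passed as `dir` or set ",
           "options(orcflow.netdata_dir = ...)", call. = FALSE)
    }
    hit <- fetched
  }
  read_graph_file(hit[1], format = "gml")
}

netdata_cache_dir <- function() {
  file.path(tempdir(), "orcflow-netdata")
}

.netdata_state <- new.env(parent = emptyenv())

#' @rdname load_netdata
#' @export
fetch_netdata <- function(name) {
  if (isTRUE(.netdata_state$unreachable)) {
    stop("netdata host unreachable (cached for this session)", call. = FALSE)
  }
  cache <- netdata_cache_dir()
  dir.create(cache, showWarnings = FALSE, recursive = TRUE)
  zip <- file.path(cache, paste0(name, ".zip"))
  url <- paste0("http://www-personal.umich.edu/~mejn/netdata/", name, ".zip")
  old <- options(timeout = 20)
  on.exit(options(old), add = TRUE)
  ok <- tryCatch(utils::download.file(url, zip, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    .netdata_state$unreachable <- TRUE
    stop("could not download ", url, call. = FALSE)
  }
  utils::unzip(zip, exdir = cache, junkpaths = TRUE)
  file.path(cache, paste0(name, ".gml"))
}

#' Ground-truth conference labels for the football network
#'
#' The football GML encodes each team's conference in the node `value`
#' attribute; this helper turns any numeric node attribute of a loaded
#' graph into a partition.
#'
#' @param graph A graph whose vertices carry a `value` attribute.
#' @param attr Attribute name holding the labels.
#' @return A partition tibble.
#' @export
partition_from_attribute <- function(graph, attr = "value") {
  v <- igraph::vertex_attr(graph, attr)
  if (is.null(v)) stop("graph has no vertex attribute '", attr, "'",
                       call. = FALSE)
  as_partition(stats::setNames(as.character(v), igraph::V(graph)$name))
}
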