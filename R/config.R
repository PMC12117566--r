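# Flat key/value config document mirroring the CLI grammar one-to-one.
# Each CLI flag has exactly one config key; repeatable flags map to YAML
# sequences of the same argument strings.

num_tok <- function(x) as.numeric(x)

split_tokens <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]

# polygon <-> "x1,y1;x2,y2;..." ; circle pore "cx,cy,r"
format_poly <- function(poly) {
  paste(apply(poly, 1, function(v) paste(fmt_num(v), collapse = ",")), collapse = ";")
}
parse_poly_or_circle <- function(s) {
  parts <- strsplit(s, ";")[[1]]
  nums <- lapply(parts, function(p) as.numeric(strsplit(p, ",")[[1]]))
  if (length(nums) == 1 && length(nums[[1]]) == 3) {
    v <- nums[[1]]
    return(disc_polygon(v[1], v[2], v[3]))
  }
  if (any(vapply(nums, length, integer(1)) != 2) || length(nums) < 3)
    stop_cg("parse_error", sprintf("bad polygon token '%s'", s))
  m <- do.call(rbind, nums)
  colnames(m) <- c("x", "y")
  m
}

#' @rdname cli_build
#' @param s a membrane argument string, e.g.
#'   `"lipid:POPC:5 lipid:DOPC:5 apl:0.6 zc:5"`
#' @export
parse_membrane_arg <- function(s) {
  comp_u <- numeric(0); comp_l <- numeric(0); comp_b <- numeric(0)
  apl <- 0.6; apl_u <- NA; apl_l <- NA; zc <- NULL; thickness <- 2
  leaflets <- "both"; boundary <- NULL; pores <- list()
  for (tok in split_tokens(s)) {
    kv <- strsplit(tok, ":")[[1]]
    key <- kv[1]
    switch(key,
      lipid  = { comp_b[kv[2]] <- num_tok(kv[3]) },
      ulipid = { comp_u[kv[2]] <- num_tok(kv[3]) },
      llipid = { comp_l[kv[2]] <- num_tok(kv[3]) },
      apl = { apl <- num_tok(kv[2]) },
      uapl = { apl_u <- num_tok(kv[2]) },
      lapl = { apl_l <- num_tok(kv[2]) },
      zc = { zc <- num_tok(kv[2]) },
      thickness = { thickness <- num_tok(kv[2]) },
      leaflets = { leaflets <- kv[2] },
      patch = { boundary <- parse_poly_or_circle(paste(kv[-1], collapse = ":")) },
      pore = { pores[[length(pores) + 1L]] <- parse_poly_or_circle(paste(kv[-1], collapse = ":")) },
      stop_cg("parse_error", sprintf("unknown membrane token '%s'", tok))
    )
  }
  cu <- if (length(comp_u) > 0) comp_u else comp_b
  cl <- if (length(comp_l) > 0) comp_l else comp_b
  if (length(cu) == 0 || length(cl) == 0)
    stop_cg("parse_error", "membrane argument needs at least one lipid:NAME:RATIO token")
  membrane_spec(composition = cu, apl = if (is.na(apl_u)) apl else apl_u,
                zc = zc, thickness = thickness,
                composition_lower = cl,
                apl_lower = if (is.na(apl_l)) apl else apl_l,
                leaflets = leaflets, boundary = boundary, pores = pores)
}

format_membrane_arg <- function(m) {
  toks <- character(0)
  same <- identical(m$composition, m$composition_lower)
  if (same) {
    for (n in names(m$composition))
      toks <- c(toks, sprintf("lipid:%s:%s", n, fmt_num(m$composition[[n]])))
  } else {
    for (n in names(m$composition))
      toks <- c(toks, sprintf("ulipid:%s:%s", n, fmt_num(m$composition[[n]])))
    for (n in names(m$composition_lower))
      toks <- c(toks, sprintf("llipid:%s:%s", n, fmt_num(m$composition_lower[[n]])))
  }
  if (isTRUE(all.equal(m$apl, m$apl_lower))) {
    toks <- c(toks, sprintf("apl:%s", fmt_num(m$apl)))
  } else {
    toks <- c(toks, sprintf("uapl:%s", fmt_num(m$apl)),
              sprintf("lapl:%s", fmt_num(m$apl_lower)))
  }
  if (!is.null(m$zc)) toks <- c(toks, sprintf("zc:%s", fmt_num(m$zc)))
  toks <- c(toks, sprintf("thickness:%s", fmt_num(m$thickness)))
  if (m$leaflets != "both") toks <- c(toks, sprintf("leaflets:%s", m$leaflets))
  if (!is.null(m$boundary)) toks <- c(toks, sprintf("patch:%s", format_poly(m$boundary)))
  for (p in m$pores) toks <- c(toks, sprintf("pore:%s", format_poly(p)))
  paste(toks, collapse = " ")
}

parse_protein_arg <- function(s) {
  file <- NULL; cx <- 0; cy <- 0; cz <- 0; rotz <- 0
  for (tok in split_tokens(s)) {
    kv <- strsplit(tok, ":")[[1]]
    switch(kv[1],
      file = { file <- paste(kv[-1], collapse = ":") },
      cx = { cx <- num_tok(kv[2]) }, cy = { cy <- num_tok(kv[2]) },
      cz = { cz <- num_tok(kv[2]) }, rotz = { rotz <- num_tok(kv[2]) },
      stop_cg("parse_error", sprintf("unknown protein token '%s'", tok)))
  }
  if (is.null(file)) stop_cg("parse_error", "protein argument needs file:PATH")
  protein_spec(file, cx, cy, cz, rotz)
}

format_protein_arg <- function(p) {
  toks <- sprintf("file:%s", p$file)
  for (f in c("cx", "cy", "cz", "rotz"))
    if (p[[f]] != 0) toks <- c(toks, sprintf("%s:%s", f, fmt_num(p[[f]])))
  paste(toks, collapse = " ")
}

parse_solvation_arg <- function(s) {
  solvents <- numeric(0); salt <- NULL
  neut <- "add"; mode <- "beads"
  for (tok in split_tokens(s)) {
    kv <- strsplit(tok, ":")[[1]]
    switch(kv[1],
      solvent = { solvents[kv[2]] <- num_tok(kv[3]) },
      salt = { salt <- list(pos = kv[2], neg = kv[3], molarity = num_tok(kv[4])) },
      neutral = { neut <- kv[2] },
      mode = { mode <- kv[2] },
      stop_cg("parse_error", sprintf("unknown solvation token '%s'", tok)))
  }
  solvation_spec(solvents, salt, neutralization = neut, ratio_mode = mode)
}

format_solvation_arg <- function(sv) {
  toks <- character(0)
  for (n in names(sv$solvents))
    toks <- c(toks, sprintf("solvent:%s:%s", n, fmt_num(sv$solvents[[n]])))
  if (!is.null(sv$salt))
    toks <- c(toks, sprintf("salt:%s:%s:%s", sv$salt$pos, sv$salt$neg,
                            fmt_num(sv$salt$molarity)))
  toks <- c(toks, sprintf("neutral:%s", sv$neutralization),
            sprintf("mode:%s", sv$ratio_mode))
  paste(toks, collapse = " ")
}

parse_flood_arg <- function(s) {
  solute <- NULL; count <- NULL; molarity <- NULL
  for (tok in split_tokens(s)) {
    kv <- strsplit(tok, ":")[[1]]
    switch(kv[1],
      solute = {
        solute <- kv[2]
        if (length(kv) == 4 && kv[3] == "mol") molarity <- num_tok(kv[4])
        else if (length(kv) == 3) count <- as.integer(kv[3])
      },
      stop_cg("parse_error", sprintf("unknown flood token '%s'", tok)))
  }
  if (is.null(solute)) stop_cg("parse_error", "flood argument needs solute:NAME:COUNT")
  flood_spec(solute, count, molarity)
}

format_flood_arg <- function(fl) {
  if (!is.null(fl$count)) sprintf("solute:%s:%d", fl$solute, fl$count)
  else sprintf("solute:%s:mol:%s", fl$solute, fmt_num(fl$molarity))
}

#' Serialize a system spec to the flat config document
#'
#' The config is one flat key/value document in YAML syntax whose keys mirror
#' the CLI flags one-to-one; [config_to_spec()] inverts it exactly, so
#' `config_to_spec(spec_to_config(spec))` compares equal field-by-field.
#'
#' @param spec a [system_spec()]
#' @return named list (YAML-ready)
#' @export
spec_to_config <- function(spec) {
  cfg <- list(box = paste(fmt_num(c(spec$box$x, spec$box$y, spec$box$z)),
                          collapse = " "),
              seed = spec$seed)
  if (length(spec$membranes) > 0)
    cfg$membrane <- vapply(spec$membranes, format_membrane_arg, character(1))
  if (length(spec$proteins) > 0)
    cfg$protein <- vapply(spec$proteins, format_protein_arg, character(1))
  if (!is.null(spec$solvation)) cfg$solvation <- format_solvation_arg(spec$solvation)
  if (length(spec$flooding) > 0)
    cfg$flood <- vapply(spec$flooding, format_flood_arg, character(1))
  for (k in c("gro", "top", "pdb"))
    if (!is.null(spec$output[[k]])) cfg[[paste0("out_", k)]] <- spec$output[[k]]
  cfg
}

#' Parse the flat config document back into a system spec
#' @param cfg named list as produced by [spec_to_config()] or read from YAML
#' @return a [system_spec()]
#' @export
config_to_spec <- function(cfg) {
  bx <- as.numeric(split_tokens(cfg$box))
  if (length(bx) != 3) stop_cg("parse_error", "box must give three lengths")
  out <- list()
  for (k in c("gro", "top", "pdb"))
    if (!is.null(cfg[[paste0("out_", k)]])) out[[k]] <- cfg[[paste0("out_", k)]]
  system_spec(
    box = cg_box(bx[1], bx[2], bx[3]),
    membranes = lapply(cfg$membrane %||% character(0), parse_membrane_arg),
    proteins = lapply(cfg$protein %||% character(0), parse_protein_arg),
    solvation = if (!is.null(cfg$solvation)) parse_solvation_arg(cfg$solvation),
    flooding = lapply(cfg$flood %||% character(0), parse_flood_arg),
    output = out,
    seed = as.integer(cfg$seed %||% 1L)
  )
}

#' Write / read a spec config file (YAML)
#' @param spec a [system_spec()]
#' @param path file path
#' @export
write_config <- function(spec, path) {
  yaml::write_yaml(spec_to_config(spec), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config_to_spec(yaml::read_yaml(path))
}
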