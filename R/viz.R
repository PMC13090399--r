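# Plot exports: 2D PC scatter plots with per-group convex hulls (SVG) and a
# small self-contained interactive 3D scatter (HTML/canvas; no external
# dependencies, since no R 3D-HTML package is available in this stack).

group_palette <- function(groups) {
  base <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e", "#e6ab02")
  setNames(rep(base, length.out = length(groups)), groups)
}

#' PC scatter plot with per-group convex hulls
#'
#' Plots two PC score columns, draws the convex hull around the extreme
#' points of each group (no confidence interpretation), and optionally
#' overlays projected specimens as filled stars.
#'
#' @param space a `shape_space` with PCA fields.
#' @param study data.frame with `specimen_id` and `group`.
#' @param pcs length-2 integer vector of components (default `c(1, 2)`).
#' @param file optional SVG output path; `NULL` plots to the active device.
#' @param projected optional named list of score vectors (from
#'   [project_specimen()]) drawn on top.
#' @return The file path (or `NULL`), invisibly.
#' @export
plot_pc_scatter <- function(space, study, pcs = c(1, 2), file = NULL,
                            projected = NULL) {
  sc <- space$pc_scores[, pcs, drop = FALSE]
  grp <- study$group[match(rownames(sc), study$specimen_id)]
  pal <- group_palette(unique(grp[!is.na(grp)]))
  vf <- 100 * space$variance_fraction[pcs]
  if (!is.null(file)) {
    grDevices::svg(file, width = 7, height = 6)
    on.exit(grDevices::dev.off())
  }
  plot(sc, type = "n",
       xlab = sprintf("PC%d (%.2f%%)", pcs[1], vf[1]),
       ylab = sprintf("PC%d (%.2f%%)", pcs[2], vf[2]))
  for (g in names(pal)) {
    m <- sc[which(grp == g), , drop = FALSE]
    if (nrow(m) >= 3) {
      h <- grDevices::chull(m)
      graphics::polygon(m[h, 1], m[h, 2],
                        border = pal[g],
                        col = grDevices::adjustcolor(pal[g], alpha.f = 0.15))
    }
    graphics::points(m, pch = 19, col = pal[g])
  }
  if (!is.null(projected))
    for (nm in names(projected))
      graphics::points(projected[[nm]][pcs[1]], projected[[nm]][pcs[2]],
                       pch = 8, cex = 1.6, lwd = 2)
  graphics::legend("topright", legend = names(pal), col = pal, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(file)
}

#' Self-contained interactive 3D PC scatter (HTML)
#'
#' Writes a single HTML file with an inline canvas renderer (drag to
#' rotate, wheel to zoom) showing three PC score columns colored by group.
#'
#' @param space a `shape_space` with PCA fields.
#' @param study data.frame with `specimen_id` and `group`.
#' @param file output HTML path.
#' @param pcs length-3 integer vector of components (default `1:3`).
#' @return `file`, invisibly.
#' @export
export_scatter3d_html <- function(space, study, file, pcs = 1:3) {
  sc <- space$pc_scores[, pcs, drop = FALSE]
  grp <- study$group[match(rownames(sc), study$specimen_id)]
  pal <- group_palette(unique(grp[!is.na(grp)]))
  data <- jsonlite::toJSON(list(
    points = unname(apply(sc, 1, as.numeric, simplify = FALSE)),
    labels = rownames(sc), groups = grp,
    colors = unname(pal[grp]),
    axes = sprintf("PC%d (%.2f%%)", pcs, 100 * space$variance_fraction[pcs])),
    auto_unbox = FALSE, digits = NA)
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>PC score 3D scatter</title></head><body>",
    "<canvas id='c' width='760' height='640' style='border:1px solid #ccc'></canvas>",
    "<div id='lbl' style='font:13px sans-serif'></div>",
    "<script>",
    paste0("var D=", data, ";"),
    "var cv=document.getElementById('c'),cx=cv.getContext('2d');",
    "var rx=-0.5,ry=0.6,zoom=240,drag=false,px,py;",
    "var P=D.points,mins=[1e9,1e9,1e9],maxs=[-1e9,-1e9,-1e9];",
    "P.forEach(function(p){for(var d=0;d<3;d++){mins[d]=Math.min(mins[d],p[d]);maxs[d]=Math.max(maxs[d],p[d]);}});",
    "var ctr=[0,1,2].map(function(d){return (mins[d]+maxs[d])/2;});",
    "var spn=Math.max.apply(null,[0,1,2].map(function(d){return maxs[d]-mins[d];}))||1;",
    "function proj(p){var x=(p[0]-ctr[0])/spn,y=(p[1]-ctr[1])/spn,z=(p[2]-ctr[2])/spn;",
    " var x1=x*Math.cos(ry)+z*Math.sin(ry),z1=-x*Math.sin(ry)+z*Math.cos(ry);",
    " var y1=y*Math.cos(rx)-z1*Math.sin(rx),z2=y*Math.sin(rx)+z1*Math.cos(rx);",
    " return [cv.width/2+x1*zoom,cv.height/2-y1*zoom,z2];}",
    "function draw(){cx.clearRect(0,0,cv.width,cv.height);",
    " var q=P.map(function(p,i){var s=proj(p);return{s:s,i:i};});",
    " q.sort(function(a,b){return a.s[2]-b.s[2];});",
    " q.forEach(function(e){cx.fillStyle=D.colors[e.i]||'#333';cx.beginPath();",
    "  cx.arc(e.s[0],e.s[1],5,0,2*Math.PI);cx.fill();});",
    " cx.fillStyle='#000';cx.font='12px sans-serif';",
    " cx.fillText(D.axes.join('  |  '),10,16);}",
    "cv.onmousedown=function(e){drag=true;px=e.clientX;py=e.clientY;};",
    "window.onmouseup=function(){drag=false;};",
    "window.onmousemove=function(e){if(!drag)return;ry+=(e.clientX-px)*0.01;",
    " rx+=(e.clientY-py)*0.01;px=e.clientX;py=e.clientY;draw();};",
    "cv.onwheel=function(e){e.preventDefault();zoom*=e.deltaY<0?1.1:0.9;draw();};",
    "cv.onmousemove=function(e){var r=cv.getBoundingClientRect(),mx=e.clientX-r.left,my=e.clientY-r.top,hit='';",
    " P.forEach(function(p,i){var s=proj(p);if(Math.abs(s[0]-mx)<6&&Math.abs(s[1]-my)<6)hit=D.labels[i]+' ('+D.groups[i]+')';});",
    " document.getElementById('lbl').textContent=hit;};",
    "draw();",
    "</script></body></html>")
  writeLines(html, file)
  invisible(file)
}
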