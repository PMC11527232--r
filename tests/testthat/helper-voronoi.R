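## Independent Voronoi-cell areas via scipy.spatial (shoelace over the
## polygon vertices of each finite region). Returns NA for unbounded cells.
scipy_voronoi_areas <- function(px, py) {
  script <- "
import sys, numpy as np
from scipy.spatial import Voronoi
pts = np.loadtxt(sys.stdin)
v = Voronoi(pts)
for i in range(len(pts)):
    reg = v.regions[v.point_region[i]]
    if -1 in reg or len(reg) < 3:
        print('nan')
        continue
    poly = v.vertices[reg]
    x, y = poly[:, 0], poly[:, 1]
    a = 0.5 * abs(np.dot(x, np.roll(y, -1)) - np.dot(y, np.roll(x, -1)))
    print('%.17g' % a)
"
  inp <- paste(sprintf("%.17g %.17g", px, py), collapse = "\n")
  out <- system2("python", c("-c", shQuote(script)), input = inp,
                 stdout = TRUE)
  as.numeric(out)
}
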