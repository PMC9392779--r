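# Default pipeline configuration (all stage parameters explicit).
schema_version: 1
knn: 30                 # EMST nearest-neighbor candidates per point
percentile: 95          # edge-length cut percentile
min_size: 100           # minimum localizations per aggregate
refine_knn: 10          # per-frame refinement neighbors
refine_cutoff_nm: 400   # per-frame refinement edge cutoff
density_radius_nm: 100  # neighbor-density radius
grid_pixel_nm: 20       # area-estimation grid pixel
min_curve_points: 50    # minimum refined members for an area estimate
frame_stride: 1         # evaluate every frame
seed: 1
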