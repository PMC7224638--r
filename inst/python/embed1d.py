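"""One-dimensional UMAP embedding helper.

Reads a headerless numeric CSV (cells x features), embeds to one
component with umap-learn under a fixed random_state, and writes the
coordinates one per line. Called by targetomics::embed_1d().
"""
import argparse
import sys
import warnings

import numpy as np


def main() -> int:
    ap = argparse.ArgumentParser()
    ap.add_argument("--input", required=True)
    ap.add_argument("--output", required=True)
    ap.add_argument("--n-neighbors", type=int, default=15)
    ap.add_argument("--min-dist", type=float, default=0.1)
    ap.add_argument("--metric", default="euclidean")
    ap.add_argument("--seed", type=int, default=42)
    args = ap.parse_args()

    x = np.loadtxt(args.input, delimiter=",", ndmin=2)
    if x.shape[0] < args.n_neighbors + 1:
        sys.stderr.write("fewer cells than n_neighbors + 1\n")
        return 2

    with warnings.catch_warnings():
        warnings.simplefilter("ignore")
        import umap

        reducer = umap.UMAP(
            n_components=1,
            n_neighbors=args.n_neighbors,
            min_dist=args.min_dist,
            metric=args.metric,
            random_state=args.seed,
            n_jobs=1,
        )
        coord = reducer.fit_transform(x)
    np.savetxt(args.output, coord.ravel(), fmt="%.10g")
    return 0


if __name__ == "__main__":
    raise SystemExit(main())
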