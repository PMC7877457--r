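"""Embedding and density-clustering backend.

Called by the R package with CSV matrices; does UMAP fit/transform and
HDBSCAN so that results match the reference implementations exactly.
"""
import argparse
import pickle
import sys

import numpy as np


def read_matrix(path):
    return np.loadtxt(path, delimiter=",", ndmin=2)


def write_matrix(x, path):
    np.savetxt(path, x, delimiter=",", fmt="%.10g")


def cmd_fit(args):
    import umap

    x = read_matrix(args.infile)
    model = umap.UMAP(
        n_components=2,
        n_neighbors=args.n_neighbors,
        min_dist=args.min_dist,
        metric="euclidean",
        random_state=args.seed,
        n_jobs=1,
    )
    emb = model.fit_transform(x)
    with open(args.model, "wb") as fh:
        pickle.dump(model, fh)
    write_matrix(emb, args.out)


def cmd_transform(args):
    with open(args.model, "rb") as fh:
        model = pickle.load(fh)
    x = read_matrix(args.infile)
    write_matrix(model.transform(x), args.out)


def cmd_hdbscan(args):
    from sklearn.cluster import HDBSCAN

    x = read_matrix(args.infile)
    labels = HDBSCAN(min_cluster_size=args.min_cluster_size,
                     copy=True).fit_predict(x)
    np.savetxt(args.out, labels.astype(int), fmt="%d")


def main(argv=None):
    p = argparse.ArgumentParser()
    sub = p.add_subparsers(dest="cmd", required=True)

    f = sub.add_parser("fit")
    f.add_argument("--in", dest="infile", required=True)
    f.add_argument("--out", required=True)
    f.add_argument("--model", required=True)
    f.add_argument("--n-neighbors", type=int, default=15)
    f.add_argument("--min-dist", type=float, default=0.1)
    f.add_argument("--seed", type=int, default=42)
    f.set_defaults(func=cmd_fit)

    t = sub.add_parser("transform")
    t.add_argument("--in", dest="infile", required=True)
    t.add_argument("--out", required=True)
    t.add_argument("--model", required=True)
    t.set_defaults(func=cmd_transform)

    h = sub.add_parser("hdbscan")
    h.add_argument("--in", dest="infile", required=True)
    h.add_argument("--out", required=True)
    h.add_argument("--min-cluster-size", type=int, default=100)
    h.set_defaults(func=cmd_hdbscan)

    args = p.parse_args(argv)
    args.func(args)


if __name__ == "__main__":
    sys.exit(main())
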