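#!/usr/bin/env python
"""Batch adapter around the ViennaRNA python bindings.

Reads a JSON list of requests on stdin, writes a JSON list of responses on
stdout.  Each request: {"op": ..., "seq": ..., ...}.

ops:
  mfe       {seq, constraint?, params?, dangles?} -> {structure, energy}
  efe       {seq, constraint?, ...}               -> {efe}
  eval      {seq, structure, ...}                 -> {energy}
  pb        {seq, structure, ...}                 -> {pb}   Boltzmann prob.
  findpath  {seq, s1, s2, width?, ...}            -> {saddle, barrier}

constraint: dot-bracket hard constraint; '(' ')' enforce pairs, 'x' forces
unpaired, '.' leaves a position free (ViennaRNA -C semantics with enforced
base pairs).  params: "turner2004" (default) or "turner1999".
"""
import json
import sys

import RNA


def make_fc(seq, req, constraint=None):
    md = RNA.md()
    md.dangles = int(req.get("dangles", 2))
    fc = RNA.fold_compound(seq, md)
    if constraint:
        fc.constraints_add(
            constraint,
            RNA.CONSTRAINT_DB_DEFAULT | RNA.CONSTRAINT_DB_ENFORCE_BP)
    return fc


def load_params(req):
    if req.get("params", "turner2004") == "turner1999":
        RNA.params_load_RNA_Turner1999()
    else:
        RNA.params_load_RNA_Turner2004()


def handle(req):
    op = req["op"]
    seq = req["seq"]
    load_params(req)
    if op == "mfe":
        fc = make_fc(seq, req, req.get("constraint"))
        s, e = fc.mfe()
        return {"structure": s, "energy": round(e, 2)}
    if op == "efe":
        fc = make_fc(seq, req, req.get("constraint"))
        fc.pf()
        return {"efe": round(fc.pf()[1], 2)}
    if op == "eval":
        fc = make_fc(seq, req)
        return {"energy": round(fc.eval_structure(req["structure"]), 2)}
    if op == "pb":
        fc = make_fc(seq, req, req.get("constraint"))
        _, g = fc.pf()
        e = fc.eval_structure(req["structure"])
        kt = RNA.GASCONST * (273.15 + 37.0) / 1000.0  # kcal/mol at 37 C
        import math
        return {"pb": math.exp((g - e) / kt)}
    if op == "findpath":
        width = int(req.get("width", 10))
        md = RNA.md()
        md.dangles = int(req.get("dangles", 2))
        RNA.cvar.dangles = md.dangles
        fc = RNA.fold_compound(seq, md)
        saddle = fc.path_findpath_saddle(req["s1"], req["s2"], width) / 100.0
        e1 = fc.eval_structure(req["s1"])
        return {"saddle": saddle, "barrier": round(saddle - e1, 2)}
    raise ValueError("unknown op: %s" % op)


def main():
    reqs = json.load(sys.stdin)
    out = []
    for req in reqs:
        try:
            res = handle(req)
        except Exception as exc:  # propagate per-request failures
            res = {"error": str(exc)}
        out.append(res)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
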