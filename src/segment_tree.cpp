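#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cmath>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

// A segment tree over the elementary intervals between the sorted unique
// endpoints of the stored features. Each stored interval decomposes into
// O(log n) canonical nodes; a stabbing query walks one root-to-leaf path;
// a range query descends to the split node and harvests the flanking
// subtrees (vsplit). All coordinates are 0-based half-open.

struct SegTree {
  std::vector<long long> lo, hi;      // node interval [lo, hi)
  std::vector<int> lt, rt;            // child ids, -1 for leaf
  std::vector<std::vector<int> > pay; // canonical payload: feature ids
  std::vector<int> cnt;               // payload refs in whole subtree
  int nleaf;

  SegTree() : nleaf(0) {}

  int build(const std::vector<long long>& p, int i, int j) {
    int id = (int)lo.size();
    lo.push_back(p[i]);
    hi.push_back(p[j]);
    lt.push_back(-1);
    rt.push_back(-1);
    pay.push_back(std::vector<int>());
    cnt.push_back(0);
    if (j - i > 1) {
      int m = (i + j) / 2;
      int a = build(p, i, m);
      int b = build(p, m, j);
      lt[id] = a;
      rt[id] = b;
    }
    return id;
  }

  void init(std::vector<long long>& pts) {
    std::sort(pts.begin(), pts.end());
    pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
    nleaf = (int)pts.size() - 1;
    build(pts, 0, (int)pts.size() - 1);
  }

  // insert clipped interval [s, e); payload goes to canonical nodes only
  void insert(int id, long long s, long long e, int f) {
    if (s <= lo[id] && hi[id] <= e) {
      pay[id].push_back(f);
      return;
    }
    if (lt[id] < 0) return;
    if (s < hi[lt[id]] && lo[lt[id]] < e) insert(lt[id], s, e, f);
    if (s < hi[rt[id]] && lo[rt[id]] < e) insert(rt[id], s, e, f);
  }

  int fill_cnt(int id) {
    if (id < 0) return 0;
    cnt[id] = (int)pay[id].size() + fill_cnt(lt[id]) + fill_cnt(rt[id]);
    return cnt[id];
  }

  int depth_of(int id) const {
    if (id < 0) return 0;
    return 1 + std::max(depth_of(lt[id]), depth_of(rt[id]));
  }

  void stab(long long pos, std::vector<int>& out, long long& ops) const {
    if (lo.empty() || pos < lo[0] || pos >= hi[0]) return;
    int id = 0;
    while (id >= 0) {
      ops++;
      out.insert(out.end(), pay[id].begin(), pay[id].end());
      if (lt[id] < 0) break;
      id = (pos < hi[lt[id]]) ? lt[id] : rt[id];
    }
  }

  // harvest every feature stored in the subtree (all overlap the query when
  // the subtree interval is contained in it); empty subtrees are skipped
  void collect(int id, std::vector<int>& out, long long& ops) const {
    if (id < 0 || cnt[id] == 0) return;
    ops++;
    out.insert(out.end(), pay[id].begin(), pay[id].end());
    collect(lt[id], out, ops);
    collect(rt[id], out, ops);
  }

  void range(int id, long long qs, long long qe, std::vector<int>& out,
             long long& ops) const {
    if (id < 0 || cnt[id] == 0) return;
    if (hi[id] <= qs || lo[id] >= qe) return;
    if (qs <= lo[id] && hi[id] <= qe) {
      collect(id, out, ops);
      return;
    }
    ops++;
    // node interval intersects the query, so its canonical payload overlaps
    out.insert(out.end(), pay[id].begin(), pay[id].end());
    range(lt[id], qs, qe, out, ops);
    range(rt[id], qs, qe, out, ops);
  }
};

struct Bin {
  bool tree;
  std::vector<int> arr; // feature ids registered in this bin
  SegTree st;
  Bin() : tree(false) {}
};

struct Index {
  double bin_size;  // +Inf = one bin per chromosome
  double thr;       // tree iff bin feature count > thr (+Inf = never)
  std::vector<long long> fs, fe;
  std::vector<int> fchrom;
  std::vector<std::string> chrom_names;
  std::map<std::string, int> chrom_id;
  std::vector<std::map<long long, Bin> > bins;

  long long binno(long long pos) const {
    if (!std::isfinite(bin_size)) return 0;
    long long b = (long long)bin_size;
    return pos / b;
  }
};

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector chrom, NumericVector start,
                     NumericVector end, double bin_size,
                     double tree_threshold) {
  Index* ix = new Index();
  ix->bin_size = bin_size;
  ix->thr = tree_threshold;
  int n = chrom.size();
  for (int i = 0; i < n; i++) {
    std::string c = as<std::string>(chrom[i]);
    int ci;
    std::map<std::string, int>::iterator it = ix->chrom_id.find(c);
    if (it == ix->chrom_id.end()) {
      ci = (int)ix->chrom_names.size();
      ix->chrom_id[c] = ci;
      ix->chrom_names.push_back(c);
      ix->bins.push_back(std::map<long long, Bin>());
    } else {
      ci = it->second;
    }
    long long s = (long long)start[i], e = (long long)end[i];
    if (e <= s) stop("feature end must exceed start");
    ix->fs.push_back(s);
    ix->fe.push_back(e);
    ix->fchrom.push_back(ci);
    long long b0 = ix->binno(s), b1 = ix->binno(e - 1);
    for (long long b = b0; b <= b1; b++) ix->bins[ci][b].arr.push_back(i);
  }
  for (size_t ci = 0; ci < ix->bins.size(); ci++) {
    for (std::map<long long, Bin>::iterator kv = ix->bins[ci].begin();
         kv != ix->bins[ci].end(); ++kv) {
      Bin& bin = kv->second;
      bool make_tree = std::isfinite(ix->thr) &&
                       (double)bin.arr.size() > ix->thr;
      if (!make_tree) continue;
      long long blo = LLONG_MIN, bhi = LLONG_MAX;
      if (std::isfinite(ix->bin_size)) {
        blo = kv->first * (long long)ix->bin_size;
        bhi = blo + (long long)ix->bin_size;
      }
      std::vector<long long> pts;
      pts.reserve(bin.arr.size() * 2);
      for (size_t k = 0; k < bin.arr.size(); k++) {
        int f = bin.arr[k];
        pts.push_back(std::max(ix->fs[f], blo));
        pts.push_back(std::min(ix->fe[f], bhi));
      }
      bin.st.init(pts);
      for (size_t k = 0; k < bin.arr.size(); k++) {
        int f = bin.arr[k];
        bin.st.insert(0, std::max(ix->fs[f], blo), std::min(ix->fe[f], bhi),
                      f);
      }
      bin.st.fill_cnt(0);
      bin.tree = true;
    }
  }
  XPtr<Index> p(ix, true);
  return p;
}

static void finish(std::vector<int>& hits) {
  std::sort(hits.begin(), hits.end());
  hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
}

static void stab_one(const Index* ix, const std::string& chrom, long long pos,
                     std::vector<int>& hits, long long& ops) {
  std::map<std::string, int>::const_iterator it = ix->chrom_id.find(chrom);
  if (it == ix->chrom_id.end() || pos < 0) return;
  const std::map<long long, Bin>& cb = ix->bins[it->second];
  std::map<long long, Bin>::const_iterator bit = cb.find(ix->binno(pos));
  if (bit == cb.end()) return;
  const Bin& bin = bit->second;
  if (bin.tree) {
    bin.st.stab(pos, hits, ops);
  } else {
    for (size_t k = 0; k < bin.arr.size(); k++) {
      int f = bin.arr[k];
      ops++;
      if (ix->fs[f] <= pos && pos < ix->fe[f]) hits.push_back(f);
    }
  }
  finish(hits);
}

static void range_one(const Index* ix, const std::string& chrom, long long qs,
                      long long qe, std::vector<int>& hits, long long& ops) {
  std::map<std::string, int>::const_iterator it = ix->chrom_id.find(chrom);
  if (it == ix->chrom_id.end()) return;
  if (qe <= qs) stop("range query needs start < end");
  if (qs < 0) qs = 0;
  const std::map<long long, Bin>& cb = ix->bins[it->second];
  long long b0 = ix->binno(qs), b1 = ix->binno(qe - 1);
  // walk only existing bins in [b0, b1]
  for (std::map<long long, Bin>::const_iterator bit = cb.lower_bound(b0);
       bit != cb.end() && bit->first <= b1; ++bit) {
    const Bin& bin = bit->second;
    if (bin.tree) {
      bin.st.range(0, qs, qe, hits, ops);
    } else {
      for (size_t k = 0; k < bin.arr.size(); k++) {
        int f = bin.arr[k];
        ops++;
        if (ix->fs[f] < qe && qs < ix->fe[f]) hits.push_back(f);
      }
    }
  }
  finish(hits);
}

// [[Rcpp::export(name = ".cpp_stab")]]
IntegerVector cpp_stab(SEXP xp, std::string chrom, double pos) {
  XPtr<Index> ix(xp);
  std::vector<int> hits;
  long long ops = 0;
  stab_one(ix, chrom, (long long)pos, hits, ops);
  IntegerVector out(hits.size());
  for (size_t i = 0; i < hits.size(); i++) out[i] = hits[i] + 1;
  return out;
}

// [[Rcpp::export(name = ".cpp_range")]]
IntegerVector cpp_range(SEXP xp, std::string chrom, double qs, double qe) {
  XPtr<Index> ix(xp);
  std::vector<int> hits;
  long long ops = 0;
  range_one(ix, chrom, (long long)qs, (long long)qe, hits, ops);
  IntegerVector out(hits.size());
  for (size_t i = 0; i < hits.size(); i++) out[i] = hits[i] + 1;
  return out;
}

// [[Rcpp::export(name = ".cpp_stab_many")]]
List cpp_stab_many(SEXP xp, CharacterVector chrom, NumericVector pos) {
  XPtr<Index> ix(xp);
  int n = chrom.size();
  List out(n);
  for (int i = 0; i < n; i++) {
    std::vector<int> hits;
    long long ops = 0;
    stab_one(ix, as<std::string>(chrom[i]), (long long)pos[i], hits, ops);
    IntegerVector v(hits.size());
    for (size_t k = 0; k < hits.size(); k++) v[k] = hits[k] + 1;
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_range_many")]]
List cpp_range_many(SEXP xp, CharacterVector chrom, NumericVector qs,
                    NumericVector qe) {
  XPtr<Index> ix(xp);
  int n = chrom.size();
  List out(n);
  for (int i = 0; i < n; i++) {
    std::vector<int> hits;
    long long ops = 0;
    range_one(ix, as<std::string>(chrom[i]), (long long)qs[i],
              (long long)qe[i], hits, ops);
    IntegerVector v(hits.size());
    for (size_t k = 0; k < hits.size(); k++) v[k] = hits[k] + 1;
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_stab_ops")]]
List cpp_stab_ops(SEXP xp, std::string chrom, double pos) {
  XPtr<Index> ix(xp);
  std::vector<int> hits;
  long long ops = 0;
  stab_one(ix, chrom, (long long)pos, hits, ops);
  IntegerVector out(hits.size());
  for (size_t i = 0; i < hits.size(); i++) out[i] = hits[i] + 1;
  return List::create(_["hits"] = out, _["ops"] = (double)ops);
}

// [[Rcpp::export(name = ".cpp_range_ops")]]
List cpp_range_ops(SEXP xp, std::string chrom, double qs, double qe) {
  XPtr<Index> ix(xp);
  std::vector<int> hits;
  long long ops = 0;
  range_one(ix, chrom, (long long)qs, (long long)qe, hits, ops);
  IntegerVector out(hits.size());
  for (size_t i = 0; i < hits.size(); i++) out[i] = hits[i] + 1;
  return List::create(_["hits"] = out, _["ops"] = (double)ops);
}

// per-bin structural summary: node counts, leaves, depth
// [[Rcpp::export(name = ".cpp_index_stats")]]
DataFrame cpp_index_stats(SEXP xp) {
  XPtr<Index> ix(xp);
  std::vector<std::string> chrom;
  std::vector<double> binno, nfeat, nnode, nleaf, depth;
  std::vector<int> is_tree;
  for (size_t ci = 0; ci < ix->bins.size(); ci++) {
    for (std::map<long long, Bin>::const_iterator kv = ix->bins[ci].begin();
         kv != ix->bins[ci].end(); ++kv) {
      const Bin& b = kv->second;
      chrom.push_back(ix->chrom_names[ci]);
      binno.push_back((double)kv->first);
      nfeat.push_back((double)b.arr.size());
      is_tree.push_back(b.tree ? 1 : 0);
      nnode.push_back(b.tree ? (double)b.st.lo.size() : NA_REAL);
      nleaf.push_back(b.tree ? (double)b.st.nleaf : NA_REAL);
      depth.push_back(b.tree ? (double)b.st.depth_of(0) : NA_REAL);
    }
  }
  return DataFrame::create(
      _["chrom"] = chrom, _["bin"] = binno, _["n_features"] = nfeat,
      _["is_tree"] = is_tree, _["n_nodes"] = nnode, _["n_leaves"] = nleaf,
      _["depth"] = depth, _["stringsAsFactors"] = false);
}
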