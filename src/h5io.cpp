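// Minimal HDF5 bridge: serialize a nested R list as an HDF5 file and back.
//
// Conventions:
//   * a named list            <-> an HDF5 group
//   * numeric/integer vector  <-> rank-1 dataset (double / int32)
//   * numeric/integer matrix  <-> rank-2 dataset, row-major, shape (nrow, ncol)
//     so that generic readers (e.g. h5py) see the natural (rows, cols) shape
//   * character vector        <-> rank-1 variable-length UTF-8 string dataset
//   * element named "_attrs"  <-> scalar attributes on the enclosing group
//
// Only what the two-modality result container needs; not a general rhdf5
// replacement.

#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>
#include <cstring>

using namespace Rcpp;

static void silence_hdf5_errors() {
  H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
}

// ---------------------------------------------------------------- writing

static void write_attrs(hid_t loc, List attrs) {
  CharacterVector names = attrs.names();
  for (R_xlen_t i = 0; i < attrs.size(); ++i) {
    std::string nm = as<std::string>(names[i]);
    RObject el = attrs[i];
    hid_t sp = H5Screate(H5S_SCALAR);
    if (is<CharacterVector>(el)) {
      std::string val = as<std::string>(el);
      hid_t tp = H5Tcopy(H5T_C_S1);
      H5Tset_size(tp, val.size() ? val.size() : 1);
      H5Tset_cset(tp, H5T_CSET_UTF8);
      hid_t a = H5Acreate2(loc, nm.c_str(), tp, sp, H5P_DEFAULT, H5P_DEFAULT);
      if (a < 0) stop("failed to create attribute '%s'", nm.c_str());
      H5Awrite(a, tp, val.c_str());
      H5Aclose(a); H5Tclose(tp);
    } else if (is<IntegerVector>(el) || is<LogicalVector>(el)) {
      int val = as<int>(el);
      hid_t a = H5Acreate2(loc, nm.c_str(), H5T_NATIVE_INT32, sp,
                           H5P_DEFAULT, H5P_DEFAULT);
      if (a < 0) stop("failed to create attribute '%s'", nm.c_str());
      H5Awrite(a, H5T_NATIVE_INT32, &val);
      H5Aclose(a);
    } else {
      double val = as<double>(el);
      hid_t a = H5Acreate2(loc, nm.c_str(), H5T_NATIVE_DOUBLE, sp,
                           H5P_DEFAULT, H5P_DEFAULT);
      if (a < 0) stop("failed to create attribute '%s'", nm.c_str());
      H5Awrite(a, H5T_NATIVE_DOUBLE, &val);
      H5Aclose(a);
    }
    H5Sclose(sp);
  }
}

static void write_dataset(hid_t loc, const std::string& nm, RObject el) {
  if (is<CharacterVector>(el)) {
    CharacterVector v(el);
    std::vector<const char*> ptrs(v.size());
    std::vector<std::string> store(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i) {
      store[i] = as<std::string>(v[i]);
      ptrs[i] = store[i].c_str();
    }
    hsize_t dim = (hsize_t)v.size();
    hid_t sp = H5Screate_simple(1, &dim, NULL);
    hid_t tp = H5Tcopy(H5T_C_S1);
    H5Tset_size(tp, H5T_VARIABLE);
    H5Tset_cset(tp, H5T_CSET_UTF8);
    hid_t ds = H5Dcreate2(loc, nm.c_str(), tp, sp,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (ds < 0) stop("failed to create dataset '%s'", nm.c_str());
    if (dim > 0) H5Dwrite(ds, tp, H5S_ALL, H5S_ALL, H5P_DEFAULT, ptrs.data());
    H5Dclose(ds); H5Tclose(tp); H5Sclose(sp);
    return;
  }

  const bool is_mat = Rf_isMatrix(el);
  const bool is_int = (TYPEOF(el) == INTSXP || TYPEOF(el) == LGLSXP);
  hid_t ftype = is_int ? H5T_STD_I32LE : H5T_IEEE_F64LE;
  hid_t mtype = is_int ? H5T_NATIVE_INT32 : H5T_NATIVE_DOUBLE;

  if (is_mat) {
    int nr = Rf_nrows(el), nc = Rf_ncols(el);
    hsize_t dims[2] = { (hsize_t)nr, (hsize_t)nc };
    hid_t sp = H5Screate_simple(2, dims, NULL);
    hid_t ds = H5Dcreate2(loc, nm.c_str(), ftype, sp,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (ds < 0) stop("failed to create dataset '%s'", nm.c_str());
    if (is_int) {
      IntegerMatrix M(el);
      std::vector<int> buf((std::size_t)nr * nc);
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c)
          buf[(std::size_t)r * nc + c] = M(r, c);
      H5Dwrite(ds, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
    } else {
      NumericMatrix M(el);
      std::vector<double> buf((std::size_t)nr * nc);
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c)
          buf[(std::size_t)r * nc + c] = M(r, c);
      H5Dwrite(ds, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
    }
    H5Dclose(ds); H5Sclose(sp);
  } else {
    hsize_t dim = (hsize_t)Rf_xlength(el);
    hid_t sp = H5Screate_simple(1, &dim, NULL);
    hid_t ds = H5Dcreate2(loc, nm.c_str(), ftype, sp,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (ds < 0) stop("failed to create dataset '%s'", nm.c_str());
    if (dim > 0) {
      if (is_int) {
        IntegerVector v(el);
        H5Dwrite(ds, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, &v[0]);
      } else {
        NumericVector v(el);
        H5Dwrite(ds, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, &v[0]);
      }
    }
    H5Dclose(ds); H5Sclose(sp);
  }
}

static void write_group(hid_t loc, List obj) {
  if (obj.size() == 0) return;
  CharacterVector names = obj.names();
  if (names.size() != obj.size()) stop("all list elements must be named");
  for (R_xlen_t i = 0; i < obj.size(); ++i) {
    std::string nm = as<std::string>(names[i]);
    RObject el = obj[i];
    if (nm == "_attrs") {
      write_attrs(loc, List(el));
    } else if (is<List>(el) && !Rf_isMatrix(el)) {
      hid_t g = H5Gcreate2(loc, nm.c_str(), H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
      if (g < 0) stop("failed to create group '%s'", nm.c_str());
      write_group(g, List(el));
      H5Gclose(g);
    } else if (!el.isNULL()) {
      write_dataset(loc, nm, el);
    }
  }
}

// [[Rcpp::export(name = ".cpp_h5_write")]]
void cpp_h5_write(std::string path, List obj) {
  silence_hdf5_errors();
  hid_t f = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (f < 0) stop("cannot create HDF5 file '%s'", path.c_str());
  write_group(f, obj);
  H5Fclose(f);
}

// ---------------------------------------------------------------- reading

static SEXP read_dataset(hid_t ds) {
  hid_t sp = H5Dget_space(ds);
  int rank = H5Sget_simple_extent_ndims(sp);
  std::vector<hsize_t> dims(rank > 0 ? rank : 1, 0);
  if (rank > 0) H5Sget_simple_extent_dims(sp, dims.data(), NULL);
  hid_t tp = H5Dget_type(ds);
  H5T_class_t cls = H5Tget_class(tp);
  SEXP out = R_NilValue;

  if (cls == H5T_STRING) {
    hsize_t n = rank > 0 ? dims[0] : 1;
    CharacterVector v((R_xlen_t)n);
    if (H5Tis_variable_str(tp)) {
      hid_t mem = H5Tcopy(H5T_C_S1);
      H5Tset_size(mem, H5T_VARIABLE);
      H5Tset_cset(mem, H5T_CSET_UTF8);
      std::vector<char*> buf(n, NULL);
      if (n > 0) H5Dread(ds, mem, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
      for (hsize_t i = 0; i < n; ++i) v[(R_xlen_t)i] = buf[i] ? buf[i] : "";
      if (n > 0) H5Treclaim(mem, sp, H5P_DEFAULT, buf.data());
      H5Tclose(mem);
    } else {
      std::size_t sz = H5Tget_size(tp);
      std::vector<char> buf(n * (sz + 1), '\0');
      hid_t mem = H5Tcopy(tp); // keep the file's character set
      H5Tset_size(mem, sz + 1);
      if (n > 0) H5Dread(ds, mem, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
      for (hsize_t i = 0; i < n; ++i)
        v[(R_xlen_t)i] = std::string(buf.data() + i * (sz + 1));
      H5Tclose(mem);
    }
    out = v;
  } else if (cls == H5T_INTEGER) {
    if (rank == 2) {
      int nr = (int)dims[0], nc = (int)dims[1];
      std::vector<int> buf((std::size_t)nr * nc);
      H5Dread(ds, H5T_NATIVE_INT32, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
      IntegerMatrix M(nr, nc);
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c)
          M(r, c) = buf[(std::size_t)r * nc + c];
      out = M;
    } else {
      hsize_t n = rank > 0 ? dims[0] : 1;
      IntegerVector v((R_xlen_t)n);
      if (n > 0) H5Dread(ds, H5T_NATIVE_INT32, H5S_ALL, H5S_ALL, H5P_DEFAULT, &v[0]);
      out = v;
    }
  } else { // float
    if (rank == 2) {
      int nr = (int)dims[0], nc = (int)dims[1];
      std::vector<double> buf((std::size_t)nr * nc);
      H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
      NumericMatrix M(nr, nc);
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c)
          M(r, c) = buf[(std::size_t)r * nc + c];
      out = M;
    } else {
      hsize_t n = rank > 0 ? dims[0] : 1;
      NumericVector v((R_xlen_t)n);
      if (n > 0) H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &v[0]);
      out = v;
    }
  }
  H5Tclose(tp); H5Sclose(sp);
  return out;
}

static List read_attrs(hid_t loc) {
  H5O_info2_t info;
  H5Oget_info3(loc, &info, H5O_INFO_NUM_ATTRS);
  int na = (int)info.num_attrs;
  List out(na);
  CharacterVector names(na);
  for (int i = 0; i < na; ++i) {
    hid_t a = H5Aopen_by_idx(loc, ".", H5_INDEX_NAME, H5_ITER_INC,
                             (hsize_t)i, H5P_DEFAULT, H5P_DEFAULT);
    char nm[256];
    H5Aget_name(a, sizeof(nm), nm);
    names[i] = nm;
    hid_t tp = H5Aget_type(a);
    H5T_class_t cls = H5Tget_class(tp);
    if (cls == H5T_STRING) {
      std::size_t sz = H5Tget_size(tp);
      if (H5Tis_variable_str(tp)) {
        char* buf = NULL;
        hid_t mem = H5Tcopy(tp);
        H5Aread(a, mem, &buf);
        out[i] = std::string(buf ? buf : "");
        if (buf) free(buf);
        H5Tclose(mem);
      } else {
        std::vector<char> buf(sz + 1, '\0');
        hid_t mem = H5Tcopy(tp);
        H5Tset_size(mem, sz + 1);
        H5Aread(a, mem, buf.data());
        out[i] = std::string(buf.data());
        H5Tclose(mem);
      }
    } else if (cls == H5T_INTEGER) {
      int v = 0;
      H5Aread(a, H5T_NATIVE_INT32, &v);
      out[i] = v;
    } else {
      double v = 0;
      H5Aread(a, H5T_NATIVE_DOUBLE, &v);
      out[i] = v;
    }
    H5Tclose(tp); H5Aclose(a);
  }
  out.names() = names;
  return out;
}

static List read_group(hid_t loc) {
  H5G_info_t ginfo;
  H5Gget_info(loc, &ginfo);
  int n = (int)ginfo.nlinks;
  std::vector<std::string> nms;
  List vals;
  for (int i = 0; i < n; ++i) {
    char nm[512];
    H5Lget_name_by_idx(loc, ".", H5_INDEX_NAME, H5_ITER_INC, (hsize_t)i,
                       nm, sizeof(nm), H5P_DEFAULT);
    H5O_info2_t oinfo;
    H5Oget_info_by_name3(loc, nm, &oinfo, H5O_INFO_BASIC, H5P_DEFAULT);
    if (oinfo.type == H5O_TYPE_GROUP) {
      hid_t g = H5Gopen2(loc, nm, H5P_DEFAULT);
      vals.push_back(read_group(g), nm);
      H5Gclose(g);
    } else if (oinfo.type == H5O_TYPE_DATASET) {
      hid_t ds = H5Dopen2(loc, nm, H5P_DEFAULT);
      vals.push_back(read_dataset(ds), nm);
      H5Dclose(ds);
    }
  }
  List attrs = read_attrs(loc);
  if (attrs.size() > 0) vals.push_back(attrs, "_attrs");
  return vals;
}

// [[Rcpp::export(name = ".cpp_h5_read")]]
List cpp_h5_read(std::string path) {
  silence_hdf5_errors();
  htri_t ok = H5Fis_accessible(path.c_str(), H5P_DEFAULT);
  if (ok <= 0) stop("'%s' is not a readable HDF5 file", path.c_str());
  hid_t f = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (f < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  List out = read_group(f);
  H5Fclose(f);
  return out;
}
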