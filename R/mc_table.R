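# Marching-cubes triangulation of the 2x2x2 binary cell, iso-level 0.5.
# One entry per triangle: "<config>:<9 digits>", where <config> encodes the
# inside corners (bit b set when corner (x,y,z) = (b&1, (b>>1)&1, (b>>2)&1)
# lies inside) and the 9 digits are the triangle's vertex coordinates in
# half-voxel units (0, 1, 2 = 0.0, 0.5, 1.0) in x,y,z order per vertex.
# Standard marching-cubes case resolution, frozen as package data.
mc_cell_table_raw <- paste(
  "1:010100001 2:100210201 3:001010201 3:201010210 4:021120010 5:021120001",
  "5:001120100 6:120210021 6:210201021 6:100010021 6:100021201 7:210201120",
  "7:201021120 7:201001021 8:120221210 9:210100221 9:100001221 9:010120221",
  "9:010221001 10:201100221 10:221100120 11:120221010 11:221001010",
  "11:221201001 12:010021210 12:210021221 13:100001210 13:001221210",
  "13:001021221 14:010021100 14:021201100 14:021221201 15:021201001",
  "15:021221201 16:102012001 17:010100012 17:012100102 18:201102210",
  "18:102012210 18:001100210 18:001210012 19:102012201 19:012210201",
  "19:012010210 20:010001120 20:001102120 20:012021120 20:012120102",
  "21:021120012 21:120102012 21:120100102 22:120210100 22:201100210",
  "22:100201102 22:100102001 22:012001102 22:001012010 22:021010012",
  "22:010021120 22:010120100 23:120210201 23:120201102 23:021120102",
  "23:012021102 24:102012001 24:221210120 25:010120012 25:221012120",
  "25:012221102 25:210102221 25:102210100 26:201102221 26:012221102",
  "26:221012120 26:001120012 26:120001100 27:221201102 27:010221102",
  "27:012010102 27:221010120 28:010001210 28:102210001 28:210102221",
  "28:012221102 28:221012021 29:021221012 29:221100012 29:100102012",
  "29:221210100 30:100010001 30:021102012 30:102021201 30:221201021",
  "31:201102012 31:021201012 31:221201021 32:201212102 33:100201010",
  "33:201212010 33:102001010 33:102010212 34:100210102 34:102210212",
  "35:001010102 35:010212102 35:010210212 36:201212102 36:120010021",
  "37:021102001 37:102021212 37:120212021 37:212120201 37:100201120",
  "38:212120210 38:120212021 38:102021212 38:021102010 38:100010102",
  "39:210212102 39:021210102 39:001021102 39:120210021 40:221212120",
  "40:212102120 40:201210120 40:201120102 41:100010120 41:010100001",
  "41:102001100 41:201102100 41:102201212 41:210212201 41:212210221",
  "41:120221210 41:100120210 42:212102221 42:102120221 42:102100120",
  "43:120221010 43:010221001 43:221212001 43:212102001 44:010201210",
  "44:201010102 44:021102010 44:102021212 44:221212021 45:201210100",
  "45:212102221 45:001221102 45:221001021 46:102100212 46:100021212",
  "46:021221212 46:021100010 47:221212102 47:001221102 47:021221001",
  "48:201212001 48:001212012 49:201212100 49:212010100 49:212012010",
  "50:100210001 50:210012001 50:210212012 51:010212012 51:210212010",
  "52:012021212 52:120212021 52:212120201 52:010201120 52:201010001",
  "53:212012021 53:100212021 53:120100021 53:212100201 54:010001100",
  "54:021120012 54:210012120 54:012210212 55:012021120 55:210012120",
  "55:212012210 56:012221212 56:221012120 56:001120012 56:120001210",
  "56:201210001 57:100201210 57:212120221 57:120212010 57:012010212",
  "58:100120001 58:120212001 58:212012001 58:120221212 59:010120221",
  "59:212010221 59:012010212 60:012021212 60:221212021 60:201010001",
  "60:010201210 61:221111021 61:111210021 61:100021210 61:021100012",
  "61:201012100 61:012201111 61:111212012 61:221212111 61:111201210",
  "62:221111021 62:221010111 62:010221100 62:212100221 62:100212001",
  "62:111001212 62:212012111 62:111012021 62:010001111 63:221212012",
  "63:221012021 64:122021012 65:021010122 65:010100122 65:001012122",
  "65:001122100 66:122021012 66:210201100 67:001012201 67:122201012",
  "67:201122210 67:021210122 67:210021010 68:012122010 68:010122120",
  "69:012122001 69:122100001 69:122120100 70:012100010 70:100012201",
  "70:122201012 70:201122210 70:120210122 71:122120012 71:120201012",
  "71:201001012 71:201120210 72:120021210 72:021012210 72:122221210",
  "72:122210012 73:122221120 73:210120221 73:120210100 73:120100010",
  "73:001010100 73:010001021 73:012021001 73:021012122 73:021122120",
  "74:201122221 74:122201012 74:100012201 74:012100021 74:120021100",
  "75:021010120 75:012122001 75:221001122 75:001221201 76:221210122",
  "76:210012122 76:210010012 77:221210122 77:122210012 77:210100012",
  "77:100001012 78:010012100 78:012221100 78:221201100 78:012122221",
  "79:001012122 79:221001122 79:201001221 80:122021102 80:102021001",
  "81:010100021 81:100122021 81:100102122 82:001100021 82:210021100",
  "82:021210122 82:201122210 82:122201102 83:102122021 83:210102021",
  "83:010210021 83:201102210 84:001102010 84:102120010 84:102122120",
  "85:122100102 85:120100122 86:100010001 86:210201120 86:102120201",
  "86:120102122 87:120210201 87:102120201 87:122120102 88:001120021",
  "88:120001210 88:102210001 88:210102221 88:122221102 89:120021010",
  "89:221210122 89:100122210 89:122100102 90:120001100 90:001120021",
  "90:201102221 90:122221102 91:201111221 91:201120111 91:120201010",
  "91:102010201 91:010102021 91:111021102 91:102122111 91:111122221",
  "91:120021111 92:210010001 92:122210001 92:102122001 92:210122221",
  "93:122221210 93:100122210 93:102122100 94:201111221 94:111100221",
  "94:010221100 94:221010122 94:001122010 94:122001111 94:111102122",
  "94:201102111 94:111001100 95:201102122 95:201122221 96:212122201",
  "96:122021201 96:012102201 96:012201021 97:100201102 97:212102201",
  "97:102212122 97:102122012 97:021012122 97:012021001 97:010001021",
  "97:001010100 97:001100102 98:212122210 98:021210122 98:210021100",
  "98:012100021 98:100012102 99:102001012 99:010122021 99:122010212",
  "99:210212010 100:012102010 100:201010102 100:010201120 100:212120201",
  "100:120212122 101:102001012 101:201212100 101:122100212 101:100122120",
  "102:212122210 102:120210122 102:100012102 102:012100010 103:212111210",
  "103:111102210 103:001210102 103:210001120 103:012120001 103:120012111",
  "103:111122120 103:212122111 103:111012102 104:122012102 104:012122021",
  "104:120021122 104:221120122 104:120221210 104:212210221 104:210212201",
  "104:102201212 104:122102212 105:100201210 105:021010120 105:102001012",
  "105:122221212 106:221212122 106:102021012 106:021102120 106:100120102",
  "107:122221212 107:120021010 107:102001012 108:122221212 108:210102201",
  "108:102210012 108:010012210 109:001012102 109:221212122 109:201210100",
  "110:012111010 110:111122010 110:221010122 110:010221100 110:212100221",
  "110:100212111 110:111102100 110:012102111 110:111212122 111:102001012",
  "111:212122221 112:122021212 112:021201212 112:021001201 113:212122021",
  "113:212021010 113:201212010 113:100201010 114:021001100 114:212021100",
  "114:210212100 114:021212122 115:212122021 115:010212021 115:210212010",
  "116:001201212 116:120001212 116:122120212 116:010001120 117:100201212",
  "117:122100212 117:120100122 118:212111210 118:212100111 118:100212001",
  "118:122001212 118:001122010 118:111010122 118:122120111 118:111120210",
  "118:100010111 119:212122120 119:212120210 120:221212122 120:210120201",
  "120:021201120 120:201021001 121:021010120 121:201210100 121:221212122",
  "122:001111021 122:001122111 122:122001212 122:100212001 122:212100221",
  "122:111221100 122:100120111 122:111120021 122:122221111 123:021010120",
  "123:122221212 124:201111001 124:111212001 124:122001212 124:001122010",
  "124:221010122 124:010221111 124:111210010 124:201210111 124:111221212",
  "125:212122221 125:201210100 126:001100010 126:212122221 127:221212122",
  "128:212221122 129:010100001 129:221122212 130:210221100 130:221122100",
  "130:212201100 130:212100122 131:001212201 131:212001122 131:010122001",
  "131:122010221 131:210221010 132:221120212 132:120010212 132:021122212",
  "132:021212010 133:021122001 133:212001122 133:001212100 133:221100212",
  "133:100221120 134:120021122 134:021120010 134:100010120 134:210100120",
  "134:100210201 134:221201210 134:201221212 134:122212221 134:120122221",
  "135:120210221 135:201122212 135:122201021 135:001021201 136:122212120",
  "136:120212210 137:210100212 137:001212100 137:212001122 137:010122001",
  "137:122010120 138:201100212 138:100122212 138:100120122 139:201001212",
  "139:001120212 139:120122212 139:001010120 140:122212021 140:212010021",
  "140:212210010 141:001021100 141:021212100 141:212210100 141:212021122",
  "142:122212021 142:021212010 142:212201010 142:201100010 143:021122212",
  "143:201021212 143:001021201 144:122012221 144:012001221 144:221001102",
  "144:212221102 145:010122012 145:122010221 145:100221010 145:221100212",
  "145:102212100 146:102001100 146:001102012 146:122012102 146:212122102",
  "146:122212221 146:201221212 146:221201210 146:100210201 146:102100201",
  "147:212201102 147:221122210 147:012210122 147:210012010 148:102212122",
  "148:221122212 148:122221120 148:122120021 148:010021120 148:021010012",
  "148:001012010 148:012001102 148:012102122 149:122012021 149:212221102",
  "149:120102221 149:102120100 150:120210221 150:012021122 150:100010001",
  "150:102212201 151:012021122 151:210221120 151:212201102 152:210102212",
  "152:102210001 152:120001210 152:001120012 152:122012120 153:210102212",
  "153:102210100 153:122012120 153:010120012 154:212201102 154:100012001",
  "154:012100122 154:120122100 155:010111012 155:010102111 155:102010201",
  "155:120201010 155:201120212 155:111212120 155:120122111 155:111122012",
  "155:102212111 156:012021122 156:001102010 156:212010102 156:010212210",
  "157:210111212 157:210122111 157:122210021 157:100021210 157:021100012",
  "157:111012100 157:100102111 157:111102212 157:122012111 158:102212201",
  "158:122012021 158:100010001 159:012021122 159:102212201 160:102201122",
  "160:122201221 161:221100201 161:100221010 161:122010221 161:010122001",
  "161:102001122 162:221122210 162:122100210 162:122102100 163:010210001",
  "163:210122001 163:122102001 163:122210221 164:221120201 164:010201120",
  "164:201010102 164:021102010 164:102021122 165:102001122 165:021122001",
  "165:221100201 165:100221120 166:210221120 166:122010021 166:010122100",
  "166:102100122 167:021111001 167:111120001 167:210001120 167:001210102",
  "167:221102210 167:102221111 167:111122102 167:021122111 167:111221120",
  "168:210120201 168:120102201 168:120122102 169:201210100 169:120001010",
  "169:001120102 169:122102120 170:100122102 170:100120122 171:102001010",
  "171:120102010 171:122102120 172:122102021 172:102210021 172:210010021",
  "172:102201210 173:021111001 173:021100111 173:100021210 173:122210021",
  "173:210122201 173:111201122 173:122102111 173:111102001 173:100201111",
  "174:100010021 174:122100021 174:102100122 175:021122102 175:021102001",
  "176:012001122 176:001221122 176:001201221 177:012010100 177:221012100",
  "177:201221100 177:122012221 178:210221122 178:210122012 178:100210012",
  "178:001100012 179:210221122 179:012210122 179:010210012 180:122012021",
  "180:001120010 180:120001221 180:201221001 181:221111201 181:111122201",
  "181:012201122 181:201012100 181:021100012 181:100021111 181:111120100",
  "181:221120111 181:111021122 182:120210221 182:100010001 182:122012021",
  "183:122012021 183:221120210 184:120122012 184:201120012 184:001201012",
  "184:120201210 185:010111012 185:111100012 185:201012100 185:012201122",
  "185:210122201 185:122210111 185:111120122 185:010120111 185:111210100",
  "186:122012001 186:100122001 186:120122100 187:122012010 187:122010120",
  "188:201111001 188:201012111 188:012201122 188:210122201 188:122210021",
  "188:111021210 188:210010111 188:111010001 188:012021111 189:012021122",
  "189:100201210 190:001100010 190:012021122 191:021122012 192:212221012",
  "192:012221021 193:021010221 193:100221010 193:221100212 193:001212100",
  "193:212001012 194:021210221 194:210021100 194:012100021 194:100012201",
  "194:212201012 195:210021010 195:021210221 195:001012201 195:212201012",
  "196:120010221 196:010212221 196:010012212 197:120100001 197:212120001",
  "197:012212001 197:221120212 198:210221120 198:201100212 198:010212100",
  "198:212010012 199:212111012 199:111221012 199:120012221 199:012120001",
  "199:210001120 199:001210111 199:111201001 199:212201111 199:111210221",
  "200:021012120 200:012210120 200:012212210 201:120021010 201:012100001",
  "201:100012210 201:212210012 202:012212021 202:212100021 202:100120021",
  "202:100212201 203:212111012 203:212021111 203:021212120 203:201120212",
  "203:120201010 203:111010201 203:201001111 203:111001012 203:021010111",
  "204:212010012 204:212210010 205:210100001 205:012210001 205:212210012",
  "206:212201100 206:010212100 206:012212010 207:212201001 207:212001012",
  "208:212221102 208:221001102 208:221021001 209:100102212 209:021100212",
  "209:221021212 209:100021010 210:102212201 210:221100210 210:100221001",
  "210:021001221 211:210111010 211:111201010 211:102010201 211:010102021",
  "211:212021102 211:021212111 211:111221021 211:210221111 211:111212201",
  "212:221120010 212:221010001 212:212221001 212:102212001 213:102212221",
  "213:120102221 213:100102120 214:010001100 214:212201102 214:210221120",
  "215:201102212 215:210221120 216:212210102 216:210021102 216:021001102",
  "216:210120021 217:210111212 217:111120212 217:021212120 217:212021102",
  "217:010102021 217:102010111 217:111100102 217:210100111 217:111010120",
  "218:001111021 218:111102021 218:212021102 218:021212120 218:201120212",
  "218:120201111 218:111100120 218:001100111 218:111201102 219:102212201",
  "219:021010120 220:010001102 220:212010102 220:210010212 221:210100102",
  "221:210102212 222:102212201 222:001100010 223:212201102 224:102201012",
  "224:201021012 224:201221021 225:001012102 225:010100021 225:201021100",
  "225:021201221 226:221021012 226:100221012 226:102100012 226:210221100",
  "227:210111010 227:210001111 227:001210102 227:221102210 227:102221012",
  "227:111012221 227:221021111 227:111021010 227:001012111 228:201221102",
  "228:221010102 228:010012102 228:010221120 229:221111201 229:221102111",
  "229:102221012 229:120012221 229:012120001 229:111001120 229:120100111",
  "229:111100201 229:102001111 230:012111010 230:012120111 230:120012221",
  "230:102221012 230:221102210 230:111210102 230:102100111 230:111100010",
  "230:120210111 231:001012102 231:120210221 232:210120201 232:201120102",
  "232:120021102 232:021012102 233:100201210 233:102001012 233:120021010",
  "234:120021012 234:102120012 234:100120102 235:012102001 235:021010120",
  "236:012102201 236:210012201 236:010012210 237:001012102 237:100201210",
  "238:100010012 238:100012102 239:012102001 240:201021001 240:221021201",
  "241:021010100 241:201021100 241:221021201 242:001100210 242:221001210",
  "242:021001221 243:021010210 243:021210221 244:221120010 244:001221010",
  "244:201221001 245:100201221 245:100221120 246:010001100 246:120210221",
  "247:221120210 248:201210120 248:021201120 248:001201021 249:100201210",
  "249:010120021 250:120021001 250:120001100 251:120021010 252:010001201",
  "252:010201210 253:210100201 254:100010001"
)

mc_cell_env <- new.env(parent = emptyenv())

# list indexed by config 1..254: matrix (n_tri x 9) of vertex coords
mc_cell_triangles <- function() {
  if (is.null(mc_cell_env$lut)) {
    entries <- strsplit(mc_cell_table_raw, " ", fixed = TRUE)[[1]]
    cfg <- as.integer(sub(":.*", "", entries))
    digs <- sub(".*:", "", entries)
    coords <- matrix(as.integer(unlist(strsplit(digs, ""))) / 2,
                     ncol = 9, byrow = TRUE)
    lut <- vector("list", 254L)
    for (k in seq_along(cfg)) {
      i <- cfg[k]
      lut[[i]] <- rbind(lut[[i]], coords[k, ])
    }
    mc_cell_env$lut <- lut
  }
  mc_cell_env$lut
}
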